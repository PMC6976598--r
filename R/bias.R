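#' Phenotypic-bias profile of a dose series
#'
#' In the (migration, death) score plane the diagonal `death = migration` is
#' the no-bias line. Each dose is characterized by
#'
#' * `bias` — the raw difference `death - migration`;
#' * `distance` — the signed perpendicular distance from the no-bias line,
#'   `sin(pi/4) * (death - migration)` (positive on the cytotoxic side);
#' * `angle` — the angular deviation from the no-bias line,
#'   `atan2(death, migration) - pi/4` in `[-pi/4, pi/4]`, defined as 0 when
#'   both scores are 0.
#'
#' @param scores data frame from [phenotype_scores()].
#' @return A data frame: `concentration`, `migration`, `death`, `bias`,
#'   `distance`, `angle`.
#' @export
bias_profile <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L,
            all(c("migration", "death") %in% names(scores)))
  mig <- scores$migration
  dth <- scores$death
  bias <- dth - mig
  angle <- ifelse(mig == 0 & dth == 0, 0, atan2(dth, mig) - pi / 4)
  data.frame(concentration = scores$concentration,
             migration = mig, death = dth, bias = bias,
             distance = sin(pi / 4) * bias, angle = angle,
             row.names = NULL)
}

#' Kolmogorov-Smirnov comparison of two bias samples
#'
#' Quantifies how much the per-dose phenotypic-bias distribution shifts
#' between two experimental settings (typically two seeding densities) by
#' the two-sample KS statistic `D = sup |ECDF_a - ECDF_b|`. The p-value is
#' exact (via the small-sample Smirnov distribution) when
#' `n_a * n_b <= 10^4` — always the case for the usual 8-dose series — and
#' asymptotic otherwise.
#'
#' @param bias_a,bias_b numeric samples of bias values (nonempty).
#' @param alpha significance level (default 0.05).
#' @param pair optional length-2 label for the compared settings.
#' @return A list of class `ws_ks`: `pair`, `ks_distance`, `p_value`,
#'   `significant`, `exact`.
#' @export
ks_compare <- function(bias_a, bias_b, alpha = 0.05,
                       pair = c(NA_character_, NA_character_)) {
  if (length(bias_a) == 0L || length(bias_b) == 0L)
    stop("insufficient-data error: both samples must be nonempty")
  exact <- length(bias_a) * length(bias_b) <= 1e4
  kt <- suppressWarnings(stats::ks.test(bias_a, bias_b, exact = exact))
  structure(list(pair = as.character(pair),
                 ks_distance = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 significant = unname(kt$p.value) < alpha,
                 exact = exact),
            class = "ws_ks")
}

#' @export
print.ws_ks <- function(x, ...) {
  cat("<KS comparison> ", x$pair[1L], " vs ", x$pair[2L], ": D = ",
      signif(x$ks_distance, 4), ", p = ", signif(x$p_value, 4),
      if (x$significant) " (significant)" else "", "\n", sep = "")
  invisible(x)
}

#' Classify a drug from its lumped phenotype scores
#'
#' A drug whose combined lumped activity (`migration_lumped +
#' death_lumped`) is below `activity_floor` is `inactive`. Otherwise the
#' lumped bias (`death - migration`) decides: below `-bias_floor` is
#' `migrastatic` (it delays closure by inhibiting migration), above
#' `+bias_floor` is `cytotoxic`, and in between is `balanced`.
#'
#' @param lumped a [lumped_scores()] result.
#' @param activity_floor minimum total activity (default 0.05).
#' @param bias_floor minimum |bias| to leave `balanced` (default 0.05).
#' @return One of `"migrastatic"`, `"cytotoxic"`, `"balanced"`, `"inactive"`.
#' @export
classify_drug <- function(lumped, activity_floor = 0.05, bias_floor = 0.05) {
  stopifnot(inherits(lumped, "ws_lumped"))
  if (lumped$migration_lumped + lumped$death_lumped < activity_floor)
    return("inactive")
  if (lumped$bias_lumped < -bias_floor) return("migrastatic")
  if (lumped$bias_lumped > bias_floor) return("cytotoxic")
  "balanced"
}

#' Group cell lines by their drug-bias fingerprints
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) of cell lines described by their per-drug lumped-bias vectors,
#' cut into `n_groups` groups. Rows are sorted lexicographically by cell
#' line before clustering so the result is deterministic regardless of
#' input order.
#'
#' @param bias_matrix numeric matrix, cell lines in rows (rownames
#'   required), drugs in columns; no missing entries.
#' @param n_groups number of groups to cut the tree into.
#' @return A named integer vector of group labels, plus attributes
#'   `hclust` (the dendrogram) and `method` (`"euclidean/average"`).
#' @export
cluster_cell_lines <- function(bias_matrix, n_groups) {
  bias_matrix <- as.matrix(bias_matrix)
  if (is.null(rownames(bias_matrix)))
    stop("bias_matrix needs cell-line rownames")
  if (nrow(bias_matrix) < 2L)
    stop("need >= 2 cell lines to cluster")
  if (any(!is.finite(bias_matrix)))
    stop("completeness error: bias_matrix has missing entries")
  if (n_groups < 1L || n_groups > nrow(bias_matrix))
    stop("n_groups must be in [1, number of cell lines]")
  bias_matrix <- bias_matrix[order(rownames(bias_matrix)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(bias_matrix, method = "euclidean"),
                      method = "average")
  grp <- stats::cutree(hc, k = n_groups)
  attr(grp, "hclust") <- hc
  attr(grp, "method") <- "euclidean/average"
  grp
}
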