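# Hypothesis-testing layer: Wilcoxon rank-sum (normal approximation with
# tie and continuity corrections), van Elteren's stratified rank test
# for plate/objective-blocked comparisons, Bonferroni correction and
# star-coded significance tables.

# standardized rank-sum pieces for one stratum: rank-sum W of sample a,
# its null mean and tie-corrected null variance
.ranksumPieces <- function(a, b) {
  nA <- length(a); nB <- length(b); N <- nA + nB
  r <- rank(c(a, b))
  W <- sum(r[seq_len(nA)])
  E <- nA * (N + 1) / 2
  ties <- table(r)
  tieTerm <- if (N > 1) sum(ties^3 - ties) / (N * (N - 1)) else 0
  V <- nA * nB / 12 * ((N + 1) - tieTerm)
  list(W = W, E = E, V = V, nA = nA, nB = nB)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Small untied samples (both sizes <= 10) use the exact null
#' distribution of the rank sum; otherwise the normal approximation with
#' tie correction and a 0.5 continuity correction is used. Samples tied
#' across both groups give p = 1. The reported statistic is the rank sum
#' of the first sample.
#'
#' @param a,b numeric samples (each of size >= 1)
#' @param continuity apply the continuity correction (normal path)
#' @param exact force (TRUE) or forbid (FALSE) the exact path; NULL
#'   decides by sample size and ties
#' @return list: statistic (rank sum of a), z (NA on the exact path), p,
#'   exact (logical)
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))$statistic  # 6, minimum possible
#' @export
wilcoxonRankSum <- function(a, b, continuity = TRUE, exact = NULL) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  p <- .ranksumPieces(a, b)
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- !ties && p$nA <= 10 && p$nB <= 10
  if (exact && !ties) {
    u <- p$W - p$nA * (p$nA + 1) / 2
    pv <- if (u > p$nA * p$nB / 2)
      2 * stats::pwilcox(u - 1, p$nA, p$nB, lower.tail = FALSE)
    else
      2 * stats::pwilcox(u, p$nA, p$nB)
    return(list(statistic = p$W, z = NA_real_, p = min(1, pv), exact = TRUE))
  }
  if (p$V <= 0) return(list(statistic = p$W, z = 0, p = 1, exact = FALSE))
  num <- p$W - p$E
  if (continuity) num <- sign(num) * max(abs(num) - 0.5, 0)
  z <- num / sqrt(p$V)
  list(statistic = p$W, z = z, p = 2 * stats::pnorm(-abs(z)), exact = FALSE)
}

#' Van Elteren's stratified rank test
#'
#' Combines per-stratum Wilcoxon rank-sum statistics with weights
#' 1 / (nA_s + nB_s + 1), referring the standardized sum to the normal
#' distribution (two-sided). Strata in which either group is missing are
#' dropped with a warning; no common stratum is an error. With a single
#' stratum the test reduces exactly to \code{\link{wilcoxonRankSum}}
#' (including its continuity correction); with several strata no
#' continuity correction is applied.
#'
#' @param values numeric measurements (one per bead/cell)
#' @param group group label per value
#' @param stratum stratum (plate/objective pairing) per value
#' @param groupA,groupB the two group labels to compare
#' @return list: statistic (weighted standardized sum), z, p, nStrata,
#'   n (values used)
#' @export
vanElteren <- function(values, group, stratum, groupA, groupB) {
  keep <- group %in% c(groupA, groupB)
  values <- values[keep]; group <- group[keep]; stratum <- stratum[keep]
  strata <- unique(stratum)
  S <- 0; V <- 0; used <- 0L; nUsed <- 0L
  lastA <- NULL; lastB <- NULL
  for (s in strata) {
    a <- values[stratum == s & group == groupA]
    b <- values[stratum == s & group == groupB]
    if (!length(a) || !length(b)) {
      warning("dropping stratum '", s, "': group missing")
      next
    }
    pc <- .ranksumPieces(a, b)
    wgt <- 1 / (pc$nA + pc$nB + 1)
    S <- S + wgt * (pc$W - pc$E)
    V <- V + wgt^2 * pc$V
    used <- used + 1L
    nUsed <- nUsed + pc$nA + pc$nB
    lastA <- a; lastB <- b
  }
  if (!used) stop("no stratum contains both groups")
  if (used == 1L) {
    # degenerate stratification: identical to the plain rank-sum test
    w <- wilcoxonRankSum(lastA, lastB)
    return(list(statistic = S, z = w$z, p = w$p, nStrata = 1L, n = nUsed))
  }
  if (V <= 0) return(list(statistic = S, z = 0, p = 1, nStrata = used,
                          n = nUsed))
  z <- S / sqrt(V)
  list(statistic = S, z = z, p = 2 * stats::pnorm(-abs(z)), nStrata = used,
       n = nUsed)
}

#' Bonferroni correction
#'
#' p_adj = min(1, m * p); order-preserving. The family size m may exceed
#' the number of p-values supplied.
#'
#' @param p p-values in [0, 1]
#' @param m family size (>= length(p)); default length(p)
#' @return adjusted p-values
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= number of p-values")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Star codes for adjusted p-values
#'
#' @param pAdj adjusted p-values
#' @return "***" (p < 0.001), "**" (p < 0.01), "*" (p < 0.05), else "ns"
#' @export
significanceStars <- function(pAdj) {
  ifelse(pAdj < 0.001, "***",
         ifelse(pAdj < 0.01, "**",
                ifelse(pAdj < 0.05, "*", "ns")))
}

#' Star-coded significance grid across assays and comparisons
#'
#' @param results data.frame with columns assay, comparison, p_adj
#' @return data.frame grid: one row per assay, one column per comparison,
#'   cells coded "***", "**", "*" or "ns"
#' @export
significanceTable <- function(results) {
  stopifnot(all(c("assay", "comparison", "p_adj") %in% names(results)))
  results$stars <- significanceStars(results$p_adj)
  assays <- unique(results$assay)
  comps <- unique(results$comparison)
  grid <- data.frame(assay = assays, stringsAsFactors = FALSE)
  for (cmp in comps) {
    col <- vapply(assays, function(a) {
      hit <- results$stars[results$assay == a & results$comparison == cmp]
      if (length(hit)) hit[1] else NA_character_
    }, "")
    grid[[cmp]] <- col
  }
  grid
}

#' Stratified comparisons of every group against a control
#'
#' Runs van Elteren's test (or plain Wilcoxon when \code{stratum} is
#' NULL) for each non-control group against the control, applies the
#' Bonferroni correction over the family, and star-codes the results.
#'
#' @param values,group,stratum tidy sample (stratum may be NULL)
#' @param control control group label
#' @param family Bonferroni family size; default the number of
#'   comparisons performed
#' @param assay assay label stored in the output
#' @return data.frame: assay, comparison, statistic, p_raw, p_adj, stars
#' @export
compareToControl <- function(values, group, stratum = NULL, control,
                             family = NULL, assay = "assay") {
  others <- setdiff(unique(group), control)
  if (!length(others)) stop("no non-control groups")
  res <- lapply(others, function(g) {
    t <- if (is.null(stratum)) {
      wilcoxonRankSum(values[group == g], values[group == control])
    } else {
      vanElteren(values, group, stratum, g, control)
    }
    data.frame(assay = assay, comparison = paste0(g, " vs ", control),
               statistic = t$statistic, p_raw = t$p)
  })
  res <- do.call(rbind, res)
  if (is.null(family)) family <- nrow(res)
  res$p_adj <- bonferroni(res$p_raw, m = family)
  res$stars <- significanceStars(res$p_adj)
  res
}
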