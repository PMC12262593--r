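# Group statistics: one-sided t tests with per-batch t summaries for SIM
# feature tables; normality-gated Kruskal-Wallis -> pairwise Mann-Whitney
# with Bonferroni correction; significance star annotation.

#' Significance star maps
#'
#' \code{starMapMethods} is the conventional map (* p < 0.05, ** p < 0.01,
#' *** p < 0.001) and the package default; \code{starMapStrict} is the
#' stricter variant sometimes used in figure legends (* p < 0.01,
#' ** p < 0.001, *** p < 0.0001).
#'
#' @return named numeric vector of ascending p cutoffs, names = labels.
#' @export
starMapMethods <- function() c("***" = 0.001, "**" = 0.01, "*" = 0.05)

#' @rdname starMapMethods
#' @export
starMapStrict <- function() c("***" = 0.0001, "**" = 0.001, "*" = 0.01)

#' Annotate a p value with significance stars
#'
#' Returns the label of the most extreme satisfied cutoff (strict \code{<}),
#' or \code{"ns"}.
#'
#' @param p p value in [0, 1].
#' @param map named ascending cutoffs, most extreme first (see
#'   \code{\link{starMapMethods}}).
#' @return a label string.
#' @export
significanceStars <- function(p, map = starMapMethods()) {
  stopifnot(p >= 0, p <= 1)
  if (is.unsorted(map))
    stop("star map cutoffs must be sorted in ascending order")
  hit <- which(p < map)
  if (length(hit) == 0) "ns" else names(map)[hit[1]]
}

statResult <- function(test, groupA, groupB, statistic, p, sided, nA, nB,
                       correction = "none", map = starMapMethods()) {
  data.frame(test = test, groupA = groupA, groupB = groupB,
             statistic = statistic, p = p, sided = sided, nA = nA, nB = nB,
             correction = correction,
             stars = significanceStars(min(p, 1), map),
             stringsAsFactors = FALSE)
}

#' One-sided two-sample t test
#'
#' Welch's t test by default (\code{varEqual = TRUE} for the pooled-variance
#' Student variant), with the one-sided p value for the stated direction of
#' \code{a} relative to \code{b}. Zero-variance degenerate inputs are handled
#' by convention: equal-mean constant samples give t = 0, p = 0.5; constant
#' samples with unequal means give p of 0 or 1 according to the direction.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param direction \code{"greater"} (a > b) or \code{"less"}.
#' @param varEqual pooled-variance Student t instead of Welch.
#' @param labels optional group labels \code{c(a, b)}.
#' @param map star map.
#' @return one-row data.frame (test, groups, statistic, p, sided, n, stars).
#' @export
oneSidedT <- function(a, b, direction = c("greater", "less"),
                      varEqual = FALSE, labels = c("a", "b"),
                      map = starMapMethods()) {
  direction <- match.arg(direction)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    d <- mean(a) - mean(b)
    if (d == 0) { t <- 0; p <- 0.5 }
    else {
      t <- sign(d) * Inf
      p <- if ((d > 0) == (direction == "greater")) 0 else 1
    }
  } else {
    tt <- t.test(a, b, alternative = direction, var.equal = varEqual)
    t <- unname(tt$statistic); p <- tt$p.value
  }
  statResult(if (varEqual) "t (pooled)" else "t (Welch)", labels[1],
             labels[2], t, p, direction, length(a), length(b), map = map)
}

#' Per-batch t-statistic summary
#'
#' For each batch containing both conditions, computes the t statistic of the
#' reference condition against each other condition for one feature. The sign
#' convention is positive when the reference exceeds the other condition.
#' Batches missing one of the two conditions are skipped with a message.
#'
#' @param records data.frame with at least columns \code{condition},
#'   \code{batch} and the feature column.
#' @param feature feature column name.
#' @param ref reference condition label.
#' @param others other condition labels (default: all non-reference).
#' @param direction sidedness passed to \code{\link{oneSidedT}}.
#' @param varEqual pooled-variance variant.
#' @return data.frame: batch, comparison, t, p, nRef, nOther.
#' @export
batchTSummary <- function(records, feature, ref, others = NULL,
                          direction = "greater", varEqual = FALSE) {
  stopifnot(feature %in% names(records))
  if (is.null(others)) others <- setdiff(unique(records$condition), ref)
  rows <- list()
  for (b in sort(unique(records$batch))) {
    rb <- records[records$batch == b, ]
    va <- rb[rb$condition == ref, feature, drop = TRUE]
    va <- va[!is.na(va)]
    for (other in others) {
      vb <- rb[rb$condition == other, feature, drop = TRUE]
      vb <- vb[!is.na(vb)]
      if (length(va) < 2 || length(vb) < 2) {
        message("batch ", b, ": skipping ", ref, " vs ", other,
                " (a condition is missing or has < 2 values)")
        next
      }
      r <- oneSidedT(va, vb, direction, varEqual, labels = c(ref, other))
      rows[[length(rows) + 1L]] <- data.frame(
        batch = b, comparison = paste(ref, "vs", other),
        t = r$statistic, p = r$p, nRef = length(va), nOther = length(vb))
    }
  }
  if (length(rows) == 0)
    return(data.frame(batch = integer(), comparison = character(),
                      t = numeric(), p = numeric(), nRef = integer(),
                      nOther = integer()))
  do.call(rbind, rows)
}

#' Normality gate
#'
#' Shapiro-Wilk plus Kolmogorov-Smirnov (Lilliefors-corrected, i.e. with
#' estimated mean and sd) normality checks; the verdict is
#' \code{"non-normal"} if either test rejects at \code{alpha}, routing
#' downstream analysis to the non-parametric cascade. Constant samples are
#' non-normal by convention. For n > 5000 the Shapiro-Wilk test runs on a
#' deterministic subsample of 5000 values.
#'
#' @param values numeric sample, n >= 3.
#' @param alpha rejection level.
#' @return list: \code{shapiroP}, \code{ksP}, \code{verdict}
#'   (\code{"normal"}/\code{"non-normal"}), \code{reason}.
#' @export
normalityGate <- function(values, alpha = 0.05) {
  stopifnot(length(values) >= 3)
  if (sd(values) == 0)
    return(list(shapiroP = NA_real_, ksP = NA_real_, verdict = "non-normal",
                reason = "constant sample"))
  sw <- if (length(values) > 5000)
    shapiro.test(values[round(seq(1, length(values), length.out = 5000))])
  else shapiro.test(values)
  ks <- nortest::lillie.test(values)
  verdict <- if (sw$p.value < alpha || ks$p.value < alpha) "non-normal"
             else "normal"
  list(shapiroP = sw$p.value, ksP = ks$p.value, verdict = verdict,
       reason = NA_character_)
}

#' Kruskal-Wallis omnibus with Bonferroni-corrected pairwise Mann-Whitney
#'
#' Runs the Kruskal-Wallis rank-sum test across all groups; if the omnibus
#' p value is below \code{alpha}, all pairwise two-sided Mann-Whitney
#' (Wilcoxon rank-sum) tests follow, with p values multiplied by the number
#' of comparisons performed (capped at 1). Exact Mann-Whitney p values are
#' used for small tie-free samples (both n <= 20); otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param groups named list of numeric samples (>= 2 groups, each n >= 2).
#' @param alpha omnibus gate level.
#' @param map star map.
#' @return data.frame of results: the omnibus row first, then one row per
#'   pairwise comparison (if the gate opened), with Bonferroni-corrected p.
#' @export
kruskalThenPairwise <- function(groups, alpha = 0.05,
                                map = starMapMethods()) {
  if (length(groups) < 2) stop("need at least 2 groups")
  stopifnot(all(vapply(groups, length, 1L) >= 2))
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  kw <- kruskal.test(groups)
  out <- statResult("Kruskal-Wallis", paste(names(groups), collapse = "|"),
                    "", unname(kw$statistic), kw$p.value, "two-sided",
                    sum(lengths(groups)), NA_integer_, map = map)
  if (kw$p.value >= alpha) return(out)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  for (pr in pairs) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    exact <- length(a) <= 20 && length(b) <= 20 &&
      !anyDuplicated(c(a, b))
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    out <- rbind(out, statResult("Mann-Whitney U", pr[1], pr[2],
                                 unname(wt$statistic),
                                 min(1, wt$p.value * m), "two-sided",
                                 length(a), length(b),
                                 correction = sprintf("Bonferroni (x%d)", m),
                                 map = map))
  }
  rownames(out) <- NULL
  out
}

#' Feature comparison across conditions on a feature table
#'
#' Convenience wrapper reproducing the analysis route for per-domain feature
#' tables: a normality gate on the pooled feature, then either one-sided t
#' tests of the reference against each other condition (normal route) or the
#' Kruskal-Wallis / Mann-Whitney cascade (non-normal route).
#'
#' @param features data.frame with columns \code{condition} and the feature.
#' @param feature feature column name.
#' @param ref reference condition.
#' @param direction direction for the t route ("greater": ref > other).
#' @param forceRoute NULL (gate decides), "t", or "nonparametric".
#' @param map star map.
#' @return list: \code{gate} (normality report or NULL), \code{results}
#'   (data.frame of test results).
#' @export
conditionComparison <- function(features, feature, ref,
                                direction = "greater", forceRoute = NULL,
                                map = starMapMethods()) {
  vals <- features[[feature]]
  keep <- !is.na(vals)
  features <- features[keep, ]; vals <- vals[keep]
  gate <- NULL
  route <- forceRoute
  if (is.null(route)) {
    gate <- normalityGate(vals)
    route <- if (gate$verdict == "normal") "t" else "nonparametric"
  }
  if (route == "t") {
    others <- setdiff(unique(features$condition), ref)
    res <- do.call(rbind, lapply(others, function(o)
      oneSidedT(vals[features$condition == ref],
                vals[features$condition == o], direction,
                labels = c(ref, o), map = map)))
  } else {
    res <- kruskalThenPairwise(split(vals, features$condition), map = map)
  }
  list(gate = gate, results = res)
}
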