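## Pearson screening of descriptors against activity, with removal of
## collinear descriptors before modelling.

#' Pearson correlation with a t-test p-value
#'
#' Thin wrapper around [stats::cor.test()] returning the coefficient, the
#' two-sided p-value from the exact t-transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom, and the
#' sample size, with explicit errors for degenerate inputs.
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return A list with elements \code{r}, \code{p} and \code{n}.
#' @export
#' @examples
#' pearson(1:10, (1:10) * 2 + 1)$r  # 1
pearson <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  check_finite(x, "x"); check_finite(y, "y")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

star_level <- function(p, alpha_strict, alpha_loose) {
  ifelse(p < alpha_strict, "**", ifelse(p < alpha_loose, "*", ""))
}

#' Screen descriptor columns against activity
#'
#' Correlates every column of a feature table with the activity vector,
#' annotating each with the Pearson coefficient, p-value and a star level
#' (\code{"**"} below \code{alpha_strict}, \code{"*"} below
#' \code{alpha_loose}).  Columns for which the correlation is undefined
#' (e.g. constant) are reported with an error message instead of aborting
#' the scan.  No multiple-testing correction is applied; the return value
#' carries a \code{note} attribute saying so.
#'
#' @param features Data frame or matrix of numeric descriptor columns.
#' @param activity Numeric activity vector, one value per row.
#' @param alpha_strict,alpha_loose Significance levels for the two star
#'   levels; defaults 0.01 and 0.05.
#' @return A data frame sorted by decreasing \eqn{|r|} with columns
#'   \code{feature}, \code{r}, \code{p}, \code{n}, \code{stars},
#'   \code{error}.
#' @export
screen_descriptors <- function(features, activity, alpha_strict = 0.01,
                               alpha_loose = 0.05) {
  if (alpha_strict >= alpha_loose)
    stop("alpha_strict must be below alpha_loose", call. = FALSE)
  features <- as.data.frame(features)
  res <- lapply(names(features), function(nm) {
    out <- tryCatch(pearson(features[[nm]], activity), error = identity)
    if (inherits(out, "error")) {
      data.frame(feature = nm, r = NA_real_, p = NA_real_,
                 n = length(activity), stars = "",
                 error = conditionMessage(out), stringsAsFactors = FALSE)
    } else {
      data.frame(feature = nm, r = out$r, p = out$p, n = out$n,
                 stars = star_level(out$p, alpha_strict, alpha_loose),
                 error = "", stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, res)
  res <- res[order(-abs(res$r), res$feature, na.last = TRUE), ]
  rownames(res) <- NULL
  attr(res, "note") <-
    "p-values are per-column; no multiple-testing correction applied"
  res
}

#' Drop collinear descriptors from a ranked selection
#'
#' Walks the selection in order (highest-ranked first) and drops any later
#' descriptor whose squared Pearson correlation with an already-kept one
#' reaches \code{r2_threshold}.  At the default threshold of 1 only exact
#' duplicates and negations are removed -- e.g. the chemical potential
#' given the electronegativity, which are equal and opposite by
#' construction, so carrying both is redundant.
#'
#' @param selected Character vector of column names of \code{features},
#'   ranked most-important first.
#' @param features Data frame holding those columns.
#' @param r2_threshold Squared-correlation threshold in (0, 1]; default 1.
#' @return The surviving subset of \code{selected}, order preserved.
#' @export
#' @examples
#' f <- data.frame(chi = 1:5, mu = -(1:5), A = c(2, 1, 4, 3, 5))
#' eliminate_collinear(c("chi", "mu", "A"), f)  # drops mu
eliminate_collinear <- function(selected, features, r2_threshold = 1) {
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]", call. = FALSE)
  features <- as.data.frame(features)
  miss <- setdiff(selected, names(features))
  if (length(miss))
    stop("unknown feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  kept <- character(0)
  for (nm in selected) {
    collinear <- any(vapply(kept, function(k) {
      # small slack so exact negations (squared r = 1 up to rounding)
      # are caught at the duplicate-only threshold of 1
      cor(features[[nm]], features[[k]])^2 >= r2_threshold - 1e-12
    }, logical(1)))
    if (!collinear) kept <- c(kept, nm)
  }
  kept
}

#' Write a correlation report
#'
#' Writes the output of [screen_descriptors()] as a tab-separated file,
#' rows ordered by decreasing \eqn{|r|}, with star annotations.
#'
#' @param screen Result of [screen_descriptors()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_correlation_report <- function(screen, path) {
  write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
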