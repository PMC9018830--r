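## Highly-variable-gene selection: ordinary least squares of ln(CV^2) on
## ln(mean) of the log-transformed TPM values fits the technical-noise
## baseline; genes above the fitted baseline are called variable beyond
## technical noise.  No significance margin is applied: the call is a bare
## ">" against the baseline, so under a pure noise model about half the
## genes (those with positive OLS residual) are called.

.rowVars <- function(m) {
  n <- ncol(m)
  rowSums((m - rowMeans(m))^2) / (n - 1)
}

#' Fit the mean-CV^2 technical-noise baseline
#'
#' @param x an [ExpressionMatrix-class] of `log_tpm` values.
#' @param minMean genes at or below this mean are excluded from the fit and
#'   can never be called highly variable (guards against undefined or
#'   unstable CV^2 at means near zero).
#' @param form `"loglog"` (default): OLS of `ln CV^2` on `ln mean`;
#'   `"brennecke"`: CV^2 ~ a/mean + b fit by least squares in the CV^2
#'   domain, an alternative reading of a log-linear noise fit.
#' @return a list of class `NoiseFit`: `intercept`, `slope` (loglog) or
#'   `a`, `b` (brennecke), `minMean`, `form`, and `table` (a `DataFrame`
#'   per gene: `mean`, `cv2`, `baseline`, `isHVG`).
#' @export
fitNoiseModel <- function(x, minMean = 0.1, form = c("loglog", "brennecke")) {
  form <- match.arg(form)
  if (!identical(valueKind(x), "log_tpm"))
    stop("fitNoiseModel expects log-transformed TPM values")
  if (ncol(x) < 3L) stop("need at least 3 cells")
  v <- assay(x)
  m <- rowMeans(v)
  vv <- .rowVars(v)
  cv2 <- ifelse(m > 0, vv / m^2, NA_real_)
  usable <- which(m > minMean & is.finite(cv2) & cv2 > 0)
  if (length(usable) < 10L)
    stop("fewer than 10 genes above minMean; cannot fit noise model")
  if (sd(cv2[usable]) < 1e-12 || sd(log(cv2[usable])) < 1e-12)
    stop("degenerate CV^2 values: noise fit is undefined")
  if (form == "loglog") {
    fit <- lm.fit(cbind(1, log(m[usable])), log(cv2[usable]))
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    baseline <- ifelse(m > 0, exp(a + b * log(m)), NA_real_)
    pars <- list(intercept = unname(a), slope = unname(b))
  } else {
    fit <- lm.fit(cbind(1 / m[usable], 1), cv2[usable])
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    baseline <- ifelse(m > 0, a / m + b, NA_real_)
    pars <- list(a = unname(a), b = unname(b))
  }
  isHVG <- m > minMean & is.finite(cv2) & is.finite(baseline) &
    cv2 > baseline
  tab <- DataFrame(mean = m, cv2 = cv2, baseline = baseline, isHVG = isHVG,
                   row.names = rownames(v))
  structure(c(pars, list(minMean = minMean, form = form, table = tab)),
            class = "NoiseFit")
}

#' @export
print.NoiseFit <- function(x, ...) {
  cat(sprintf("NoiseFit (%s): %d genes, %d highly variable\n", x$form,
              nrow(x$table), sum(x$table$isHVG)))
  if (x$form == "loglog")
    cat(sprintf("  ln CV^2 = %.3f %+.3f ln mean (min mean %g)\n",
                x$intercept, x$slope, x$minMean))
  invisible(x)
}

#' Highly variable genes of a noise fit
#'
#' @param fit a `NoiseFit`.
#' @return character vector of HVG ids, in matrix row order.
#' @export
hvgGenes <- function(fit) {
  stopifnot(inherits(fit, "NoiseFit"))
  rownames(fit$table)[fit$table$isHVG]
}

#' Build the informed gene set
#'
#' Union of the highly variable genes with externally supplied bulk
#' candidate genes, restricted to genes present in the fitted matrix:
#' HVGs first (matrix order), then novel candidates in input order.
#' Candidates absent from the matrix are dropped with a warning.
#'
#' @param fit a `NoiseFit`.
#' @param bulkCandidates character vector of candidate gene ids from the
#'   bulk analysis.
#' @return character vector of gene ids.
#' @export
informedGeneSet <- function(fit, bulkCandidates = character()) {
  stopifnot(inherits(fit, "NoiseFit"))
  universe <- rownames(fit$table)
  missing <- setdiff(bulkCandidates, universe)
  if (length(missing))
    warning(length(missing), " candidate gene(s) absent from the matrix ",
            "were dropped: ", paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  hvg <- hvgGenes(fit)
  c(hvg, setdiff(intersect(bulkCandidates, universe), hvg))
}
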