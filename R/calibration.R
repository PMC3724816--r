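.GAP_CHARS <- c("-", ".")

.clean_seq <- function(s) {
  x <- toupper(strsplit(s, "")[[1L]])
  x[x == "U"] <- "T"
  x
}

#' 16S rDNA substitution rate from a pairwise alignment
#'
#' S is the percentage of substituted sites among the compared alignment
#' columns. Columns containing a gap in either sequence are excluded, as
#' are columns with an ambiguity code (anything other than A, C, G, T/U)
#' in either sequence.
#'
#' @param seq1,seq2 Aligned nucleotide sequences of equal length
#'   (character strings; gaps `-` or `.`; U is treated as T).
#' @return List with `S` (percent), `compared_sites`, `substituted_sites`.
#' @export
substitution_rate <- function(seq1, seq2) {
  stopifnot(is.character(seq1), is.character(seq2),
            length(seq1) == 1L, length(seq2) == 1L)
  if (nchar(seq1) != nchar(seq2))
    stop("aligned sequences must have equal length")
  a <- .clean_seq(seq1)
  b <- .clean_seq(seq2)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  compared <- sum(ok)
  if (compared == 0L) stop("no comparable (ungapped, unambiguous) columns")
  subs <- sum(a[ok] != b[ok])
  list(S = 100 * subs / compared,
       compared_sites = compared,
       substituted_sites = subs)
}

.calib_fun <- function(form) {
  switch(form,
         exp_minus_one = function(t, c1, c2) c1 * (exp(c2 * t) - 1),
         exp           = function(t, c1, c2) c1 * exp(c2 * t),
         stop("unknown calibration form: ", form))
}

#' Fit the exponential tan(theta) -> S calibration
#'
#' Nonlinear least squares on the untransformed S scale for
#' S = const1 * (exp(const2 * tan_theta) - 1) (default, which forces
#' S(0) = 0 so identical genomes map to zero distance) or the pure
#' exponential S = const1 * exp(const2 * tan_theta). All supplied points
#' are used, including duplicates arising from multiple 16S copies per
#' genome and from the two query/reference orientations of each pair.
#'
#' @param tan_theta Numeric vector in `[0, 1]`.
#' @param S Numeric vector of substitution rates (percent), same length.
#' @param form `"exp_minus_one"` (default) or `"exp"`.
#' @param convention The tan(theta) convention the data were computed
#'   under; recorded so predictions can refuse mismatched inputs.
#' @return An object of class `ave_calibration` with components `const1`,
#'   `const2`, `r_squared`, `form`, `convention`, `n` and the fitting data.
#' @export
fit_calibration <- function(tan_theta, S,
                            form = c("exp_minus_one", "exp"),
                            convention = c("angle", "complement")) {
  form <- match.arg(form)
  convention <- match.arg(convention)
  stopifnot(length(tan_theta) == length(S))
  if (length(tan_theta) < 3L) stop("need at least 3 calibration pairs")
  if (any(tan_theta < 0 | tan_theta > 1)) stop("tan_theta outside [0, 1]")
  if (any(S < 0)) stop("negative substitution rate")
  if (diff(range(tan_theta)) < 1e-12)
    stop("degenerate calibration data: all tan_theta equal")
  f <- .calib_fun(form)
  dat <- data.frame(t = tan_theta, S = S)
  start <- list(c1 = max(S) / exp(1), c2 = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(S ~ f(t, c1, c2), data = dat, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) stop("calibration fit did not converge (start: c1=",
                             format(start$c1), ", c2=", format(start$c2),
                             "): ", conditionMessage(e)))
  co <- stats::coef(fit)
  pred <- f(tan_theta, co[["c1"]], co[["c2"]])
  ss_res <- sum((S - pred)^2)
  ss_tot <- sum((S - mean(S))^2)
  structure(list(const1 = co[["c1"]], const2 = co[["c2"]],
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 form = form, convention = convention,
                 n = length(tan_theta), data = dat),
            class = "ave_calibration")
}

#' Published calibration presets
#'
#' `"satoh2013"` carries the published constants for the exponential
#' calibration of tan(theta) against 16S rDNA substitution rates
#' (const1 = 5.0112, const2 = 2.2223, R^2 = 0.9366), fitted on 5,482
#' genome-pair points across 55 species. The preset is recorded under the
#' `exp_minus_one` form and the `angle` tan(theta) convention; users whose
#' statistics use the `complement` convention should refit.
#'
#' @param name Preset name; currently only `"satoh2013"`.
#' @return An `ave_calibration` object.
#' @export
calibration_preset <- function(name = "satoh2013") {
  if (!identical(name, "satoh2013")) stop("unknown preset: ", name)
  structure(list(const1 = 5.0112, const2 = 2.2223, r_squared = 0.9366,
                 form = "exp_minus_one", convention = "angle",
                 n = NA_integer_, data = NULL),
            class = "ave_calibration")
}

#' @export
print.ave_calibration <- function(x, ...) {
  cat("tan(theta) -> S calibration (", x$form, ", ", x$convention,
      " convention)\n", sep = "")
  cat(sprintf("  const1 = %.6g, const2 = %.6g\n", x$const1, x$const2))
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared = %.4f", x$r_squared))
  if (!is.na(x$n)) cat(sprintf("  on %d points", x$n))
  cat("\n")
  invisible(x)
}

#' @export
coef.ave_calibration <- function(object, ...) {
  c(const1 = object$const1, const2 = object$const2)
}

#' @export
summary.ave_calibration <- function(object, ...) {
  out <- unclass(object)
  if (!is.null(object$data)) {
    f <- .calib_fun(object$form)
    out$residuals <- object$data$S -
      f(object$data$t, object$const1, object$const2)
    out$rmse <- sqrt(mean(out$residuals^2))
  }
  class(out) <- "summary.ave_calibration"
  out
}

#' @export
print.summary.ave_calibration <- function(x, ...) {
  print(structure(x[c("const1", "const2", "r_squared", "form",
                      "convention", "n", "data")],
                  class = "ave_calibration"))
  if (!is.null(x$rmse)) cat(sprintf("  residual RMSE = %.4g\n", x$rmse))
  invisible(x)
}

#' @export
residuals.ave_calibration <- function(object, ...) {
  if (is.null(object$data)) stop("preset model carries no fitting data")
  f <- .calib_fun(object$form)
  object$data$S - f(object$data$t, object$const1, object$const2)
}

#' Predict S (the F distance) from tan(theta)
#'
#' Evaluates the calibration curve; strictly increasing in tan(theta).
#'
#' @param object An `ave_calibration` model.
#' @param tan_theta Values in `[0, 1]`.
#' @param convention If supplied, checked against the model's convention;
#'   a mismatch is an error since the two conventions are different scales.
#' @param ... Unused.
#' @return Numeric vector of calibrated distances (percent-substitution
#'   scale).
#' @export
predict.ave_calibration <- function(object, tan_theta, convention = NULL,
                                    ...) {
  if (!is.null(convention) && !identical(convention, object$convention))
    stop("tan(theta) convention mismatch: model is '", object$convention,
         "', input is '", convention, "'")
  if (any(tan_theta < -1e-12 | tan_theta > 1 + 1e-12))
    stop("tan_theta outside [0, 1]")
  tan_theta <- pmin(pmax(tan_theta, 0), 1)
  .calib_fun(object$form)(tan_theta, object$const1, object$const2)
}

#' @rdname predict.ave_calibration
#' @param model An `ave_calibration` model.
#' @export
tantheta_to_S <- function(model, tan_theta, convention = NULL) {
  stopifnot(inherits(model, "ave_calibration"))
  predict(model, tan_theta, convention = convention)
}

#' Invert the calibration: tan(theta) giving a target S
#'
#' Used by the synthetic generators to place genome pairs at prescribed
#' tree distances.
#'
#' @param model An `ave_calibration` model.
#' @param S Distances on the percent-substitution scale.
#' @return tan(theta) values.
#' @export
S_to_tantheta <- function(model, S) {
  stopifnot(inherits(model, "ave_calibration"))
  t <- switch(model$form,
              exp_minus_one = log(S / model$const1 + 1) / model$const2,
              exp           = log(S / model$const1) / model$const2)
  if (any(t < -1e-12 | t > 1 + 1e-12))
    stop("S outside the calibrated range (tan_theta would leave [0, 1])")
  pmin(pmax(t, 0), 1)
}

#' @export
plot.ave_calibration <- function(x, ...) {
  tt <- seq(0, 1, length.out = 200)
  curve_S <- predict(x, tt)
  if (!is.null(x$data)) {
    plot(x$data$t, x$data$S, pch = 16, cex = 0.4, col = "grey40",
         xlab = "tan(theta)", ylab = "S (% substitutions)", ...)
    lines(tt, curve_S, col = "red", lwd = 2)
  } else {
    plot(tt, curve_S, type = "l", col = "red", lwd = 2,
         xlab = "tan(theta)", ylab = "S (% substitutions)", ...)
  }
  invisible(x)
}

#' Write / read a calibration model as a key-value text file
#'
#' @param model An `ave_calibration` model.
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` returns an `ave_calibration`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "ave_calibration"))
  writeLines(c(
    paste0("form = ", model$form),
    paste0("convention = ", model$convention),
    paste0("const1 = ", format(model$const1, digits = 17)),
    paste0("const2 = ", format(model$const2, digits = 17)),
    paste0("r_squared = ", format(model$r_squared, digits = 17)),
    paste0("n = ", ifelse(is.na(model$n), "NA", model$n))
  ), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  get <- function(k) vals[match(k, keys)]
  structure(list(const1 = as.numeric(get("const1")),
                 const2 = as.numeric(get("const2")),
                 r_squared = as.numeric(get("r_squared")),
                 form = get("form"), convention = get("convention"),
                 n = suppressWarnings(as.integer(get("n"))),
                 data = NULL),
            class = "ave_calibration")
}
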