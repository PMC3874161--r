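#' Fit Michaelis-Menten aminoacylation kinetics
#'
#' Least-squares fit of v = kcat * E * S / (Km + S) to substrate/velocity
#' data by Levenberg-Marquardt. Velocities are initial rates; when product
#' time courses are measured instead, convert them with
#' [velocities_from_timecourse()]. The enzyme concentration E must be given
#' in the same units as the velocity numerator for kcat to come out in
#' min^-1; with the default E = 1, the fitted "kcat" is Vmax.
#'
#' @param substrate substrate concentrations (uM); at least 3 distinct levels
#' @param velocity initial velocities (non-negative)
#' @param enzyme enzyme concentration E (scalar)
#' @param init optional named starting values `c(kcat = , Km = )`
#' @return object of class `kinetics_fit`: list with `kcat`, `Km`,
#'   `kcat_over_Km`, `se` (named, from the fit curvature), `converged`,
#'   `fit` (the nls object), `enzyme`
#' @export
fit_michaelis_menten <- function(substrate, velocity, enzyme = 1,
                                 init = NULL) {
  if (length(substrate) != length(velocity)) {
    stop("substrate and velocity lengths differ", call. = FALSE)
  }
  if (length(unique(substrate)) < 3L) {
    stop("need at least 3 distinct substrate levels", call. = FALSE)
  }
  if (any(velocity < 0)) stop("velocities must be non-negative", call. = FALSE)
  df <- data.frame(S = substrate, v = velocity)
  if (is.null(init)) {
    vmax0 <- max(df$v) * 1.2
    km0 <- stats::median(df$S)
    init <- c(kcat = vmax0 / enzyme, Km = km0)
  }
  fit <- minpack.lm::nlsLM(v ~ kcat * enzyme * S / (Km + S), data = df,
                           start = as.list(init),
                           lower = c(kcat = 0, Km = 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    setNames(rep(NA_real_, 2L), names(co))
  })
  structure(list(kcat = unname(co[["kcat"]]), Km = unname(co[["Km"]]),
                 kcat_over_Km = unname(co[["kcat"]] / co[["Km"]]),
                 se = se, converged = fit$convInfo$isConv,
                 fit = fit, enzyme = enzyme),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> kcat %.3g min^-1, Km %.3g uM, kcat/Km %.3g uM^-1 min^-1\n",
              x$kcat, x$Km, x$kcat_over_Km))
  invisible(x)
}

#' Initial velocities from product time courses
#'
#' Fits a linear slope to the early time points of each product-vs-time
#' series, one series per substrate level. The window is the first
#' `n_points` measurements (default 3), where product formation is still
#' approximately linear.
#'
#' @param time time values
#' @param product product amounts
#' @param substrate substrate level of each measurement (groups the series)
#' @param n_points number of early points used for the slope
#' @return data.frame: `substrate`, `velocity` (slope)
#' @export
velocities_from_timecourse <- function(time, product, substrate,
                                       n_points = 3L) {
  df <- data.frame(time = time, product = product, substrate = substrate)
  out <- lapply(split(df, df$substrate), function(d) {
    d <- d[order(d$time), ][seq_len(min(n_points, nrow(d))), ]
    sl <- coef(stats::lm(product ~ time, data = d))[["time"]]
    data.frame(substrate = d$substrate[1L], velocity = sl)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$substrate), ]
}

#' Relative catalytic efficiency
#'
#' 100 * (kcat/Km) / (kcat/Km)_reference, rounded to the nearest integer as
#' efficiency tables conventionally display it. Accepts `kinetics_fit`
#' objects or bare kcat/Km ratios, so efficiencies can be recomputed directly
#' from published kcat/Km columns. Scale-invariant: multiplying both
#' efficiencies by a constant leaves the result unchanged; the reference
#' relative to itself is 100.
#'
#' @param fit a `kinetics_fit` or a numeric kcat/Km value
#' @param reference a `kinetics_fit` or numeric kcat/Km of the reference
#' @return integer percent
#' @examples
#' relative_efficiency(2.2, 5.3)   # 42
#' relative_efficiency(0.65, 5.3)  # 12
#' @export
relative_efficiency <- function(fit, reference) {
  num <- if (inherits(fit, "kinetics_fit")) fit$kcat_over_Km else as.numeric(fit)
  den <- if (inherits(reference, "kinetics_fit")) reference$kcat_over_Km
         else as.numeric(reference)
  if (!is.finite(den) || den <= 0) {
    stop("reference kcat/Km must be positive", call. = FALSE)
  }
  as.integer(round(100 * num / den))
}

#' Read a kinetics TSV
#'
#' Accepts either direct (substrate, velocity) columns or a
#' (time, product, substrate) time course, which is converted via
#' [velocities_from_timecourse()].
#'
#' @param path TSV path
#' @param n_points slope window for time-course input
#' @return data.frame with `substrate`, `velocity`
#' @export
read_kinetics_tsv <- function(path, n_points = 3L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (all(c("substrate", "velocity") %in% names(df))) {
    return(df[, c("substrate", "velocity")])
  }
  if (all(c("time", "product", "substrate") %in% names(df))) {
    return(velocities_from_timecourse(df$time, df$product, df$substrate,
                                      n_points = n_points))
  }
  stop("kinetics TSV needs (substrate, velocity) or (time, product, substrate)",
       call. = FALSE)
}
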