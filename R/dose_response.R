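# SRB viability normalization, four-parameter logistic (variable-slope)
# dose-response fitting, IC50 extraction and fold-resistance.

#' Normalize an SRB viability plate
#'
#' Subtracts the mean background absorbance and scales to the mean untreated
#' absorbance: `response = (A - mean(bg)) / (mean(untreated) - mean(bg))`.
#' Duplicate wells at a concentration are kept as separate points.
#'
#' @param plate Tibble with columns `well`, `concentration_nM`,
#'   `absorbance_490`, `role` (`treated`, `untreated`, `background`).
#' @return Tibble `concentration_nM`, `response` (treated wells only).
#' @export
normalize_srb <- function(plate) {
  stopifnot(all(c("concentration_nM", "absorbance_490", "role") %in%
                  names(plate)))
  bg_rows <- plate$role == "background"
  ut_rows <- plate$role == "untreated"
  if (!any(bg_rows) || !any(ut_rows)) {
    stop("plate needs at least one background and one untreated well",
         call. = FALSE)
  }
  bg <- mean(plate$absorbance_490[bg_rows])
  ut <- mean(plate$absorbance_490[ut_rows])
  if (ut <= bg) {
    stop("untreated signal does not exceed background; assay failure",
         call. = FALSE)
  }
  plate |>
    dplyr::filter(.data$role == "treated") |>
    dplyr::transmute(
      concentration_nM = .data$concentration_nM,
      response = (.data$absorbance_490 - bg) / (ut - bg)
    )
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `response = bottom + (top - bottom) /
#' (1 + 10^(hill * (log10(conc) - log_ic50)))` (log[inhibitor] vs response,
#' variable slope), by Levenberg-Marquardt with a data-driven start and
#' jittered multi-start restarts; the best residual sum of squares wins.
#' Parameters are unconstrained; `bottom` may go negative.
#'
#' @param data Tibble with columns `concentration_nM` (> 0) and `response`
#'   (e.g. [normalize_srb()] output). Zero-concentration rows are dropped.
#' @param n_restarts Jittered restarts beyond the data-driven start.
#' @param seed Seed for the restart jitter.
#' @return A `fourpl_fit` object: fields `bottom`, `top`, `hill`,
#'   `log_ic50`, `ic50`, `rss`, `converged`, `n`, `data`, `fit` (the
#'   underlying `nls` object or `NULL`).
#' @export
fit_4pl <- function(data, n_restarts = 5L, seed = 1L) {
  stopifnot(all(c("concentration_nM", "response") %in% names(data)))
  df <- data |>
    dplyr::filter(.data$concentration_nM > 0,
                  is.finite(.data$response)) |>
    dplyr::transmute(lc = log10(.data$concentration_nM),
                     response = .data$response)
  if (length(unique(df$lc)) < 4L) {
    stop("need at least 4 distinct positive concentrations", call. = FALSE)
  }
  unfit <- structure(
    list(bottom = NA_real_, top = NA_real_, hill = NA_real_,
         log_ic50 = NA_real_, ic50 = NA_real_, rss = NA_real_,
         converged = FALSE, n = nrow(df), data = df, fit = NULL),
    class = "fourpl_fit")
  if (diff(range(df$response)) < 1e-9) return(unfit)  # flat: unidentifiable

  bottom0 <- min(df$response)
  top0 <- max(df$response)
  half <- (bottom0 + top0) / 2
  lic0 <- df$lc[which.min(abs(df$response - half))]
  hill0 <- if (stats::cor(df$lc, df$response) <= 0) 1 else -1
  starts <- withr::with_seed(seed, {
    c(list(c(bottom0, top0, lic0, hill0)),
      purrr::map(seq_len(n_restarts), function(i) {
        c(bottom0 + rnorm(1, 0, 0.05 * (top0 - bottom0)),
          top0 + rnorm(1, 0, 0.05 * (top0 - bottom0)),
          lic0 + rnorm(1, 0, 0.3),
          hill0 * exp(rnorm(1, 0, 0.2)))
      }))
  })

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ bottom + (top - bottom) /
          (1 + 10^(hill * (lc - log_ic50))),
        data = df,
        start = list(bottom = s[1], top = s[2], log_ic50 = s[3],
                     hill = s[4]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(unfit)
  cf <- stats::coef(best$fit)
  structure(
    list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
         hill = unname(cf["hill"]), log_ic50 = unname(cf["log_ic50"]),
         ic50 = unname(10^cf["log_ic50"]), rss = best$rss,
         converged = is.finite(best$rss), n = nrow(df), data = df,
         fit = best$fit),
    class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<fourpl_fit> not converged (n =", x$n, "points)\n")
  } else {
    cat(sprintf(
      "<fourpl_fit> IC50 = %.4g nM  hill = %.3g  bottom = %.3g  top = %.3g  (rss %.3g, n %d)\n",
      x$ic50, x$hill, x$bottom, x$top, x$rss, x$n))
  }
  invisible(x)
}

#' @rdname fit_4pl
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @method tidy fourpl_fit
#' @export
tidy.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric()))
  }
  se <- tryCatch(sqrt(diag(stats::vcov(x$fit))), error = function(e) {
    setNames(rep(NA_real_, 4L), c("bottom", "top", "log_ic50", "hill"))
  })
  terms <- c("bottom", "top", "log_ic50", "hill")
  tibble::tibble(term = terms,
                 estimate = unlist(x[terms]),
                 std.error = unname(se[terms]))
}

#' @rdname fit_4pl
#' @method glance fourpl_fit
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, hill = x$hill, bottom = x$bottom,
                 top = x$top, rss = x$rss, converged = x$converged,
                 n = x$n)
}

#' @rdname fit_4pl
#' @param object A `fourpl_fit`.
#' @method autoplot fourpl_fit
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  stopifnot(object$converged)
  grid <- tibble::tibble(lc = seq(min(object$data$lc) - 0.2,
                                  max(object$data$lc) + 0.2,
                                  length.out = 200))
  grid$response <- object$bottom + (object$top - object$bottom) /
    (1 + 10^(object$hill * (grid$lc - object$log_ic50)))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$lc, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$log_ic50, linetype = "dashed") +
    ggplot2::labs(x = "log10 concentration (nM)",
                  y = "normalized response") +
    ggplot2::theme_minimal()
}

#' Fold resistance between two fitted lines
#'
#' @param clone,reference Converged [fit_4pl()] objects for the resistant
#'   clone and the reference (parental) line.
#' @return Tibble `clone_ic50`, `reference_ic50`, `fold`.
#' @export
fold_resistance <- function(clone, reference) {
  stopifnot(inherits(clone, "fourpl_fit"), inherits(reference, "fourpl_fit"))
  if (!clone$converged || !reference$converged) {
    stop("both fits must be converged", call. = FALSE)
  }
  tibble::tibble(
    clone_ic50 = clone$ic50,
    reference_ic50 = reference$ic50,
    fold = clone$ic50 / reference$ic50
  )
}
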