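#' Clinical endpoint parameters for the linear-quadratic BED
#'
#' Bundles the radiobiological parameters of one clinical endpoint: the
#' alpha/beta ratio (Gy), the linear radiosensitivity alpha (1/Gy), the
#' effective cell doubling time Teff (days) and whether the repopulation
#' correction applies. Repopulation is modelled for acute-responding tissue
#' only; late-responding tissue does not usually repopulate during the course
#' of irradiation, so its correction is identically zero.
#'
#' @param name endpoint label.
#' @param alpha_beta alpha/beta ratio in Gy (> 0).
#' @param alpha linear coefficient in 1/Gy (> 0); default 0.3.
#' @param teff effective doubling time in days (> 0); default 13.
#' @param includes_repopulation logical; subtract the repopulation term?
#' @return an object of class `endpoint_params`.
#' @export
endpoint_params <- function(name, alpha_beta, alpha = 0.3, teff = 13,
                            includes_repopulation = FALSE) {
  stopifnot(alpha_beta > 0, alpha > 0, teff > 0)
  structure(list(name = as.character(name), alpha_beta = alpha_beta,
                 alpha = alpha, teff = teff,
                 includes_repopulation = isTRUE(includes_repopulation)),
            class = "endpoint_params")
}

#' @export
print.endpoint_params <- function(x, ...) {
  cat(sprintf("Endpoint '%s': alpha/beta = %g Gy, alpha = %g /Gy, Teff = %g d, repopulation %s\n",
              x$name, x$alpha_beta, x$alpha, x$teff,
              if (x$includes_repopulation) "on" else "off"))
  invisible(x)
}

#' Default clinical endpoint registry
#'
#' The five endpoints evaluated for accelerated partial-breast HDR
#' brachytherapy: late effects fibrosis (alpha/beta 2 Gy) and telangiectasia
#' (4 Gy) without repopulation, acute effects erythema (8 Gy) and
#' desquamation (11 Gy) with repopulation, and breast carcinoma (4 Gy,
#' repopulation off by default but switchable).
#'
#' @param carcinoma_repopulation logical; enable the repopulation term for
#'   the breast-carcinoma entry.
#' @return named list of `endpoint_params`.
#' @export
default_endpoints <- function(carcinoma_repopulation = FALSE) {
  list(
    fibrosis        = endpoint_params("fibrosis", 2, includes_repopulation = FALSE),
    telangiectasia  = endpoint_params("telangiectasia", 4, includes_repopulation = FALSE),
    erythema        = endpoint_params("erythema", 8, includes_repopulation = TRUE),
    desquamation    = endpoint_params("desquamation", 11, includes_repopulation = TRUE),
    breast_carcinoma = endpoint_params("breast_carcinoma", 4,
                                       includes_repopulation = carcinoma_repopulation)
  )
}

#' Fractionation scheme
#'
#' @param n_fractions number of fractions (>= 1).
#' @param fraction_dose prescribed dose per fraction in Gy (> 0).
#' @param elapsed_time overall treatment time T in days (>= 0), entering the
#'   repopulation term only. Default 5.5 days, a typical twice-daily course
#'   of ten fractions.
#' @return an object of class `fractionation_scheme`.
#' @export
fractionation_scheme <- function(n_fractions = 10, fraction_dose = 3.4,
                                 elapsed_time = 5.5) {
  stopifnot(n_fractions >= 1, fraction_dose > 0, elapsed_time >= 0)
  structure(list(n_fractions = as.integer(n_fractions),
                 fraction_dose = fraction_dose,
                 elapsed_time = elapsed_time),
            class = "fractionation_scheme")
}

#' @export
print.fractionation_scheme <- function(x, ...) {
  cat(sprintf("Scheme: %d x %g Gy = %g Gy over %g days\n",
              x$n_fractions, x$fraction_dose,
              x$n_fractions * x$fraction_dose, x$elapsed_time))
  invisible(x)
}
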