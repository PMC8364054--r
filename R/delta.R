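# Delta-learning: the network learns the correction from a classical
# docking score (converted to pK) to the experimental affinity, and the
# final score is baseline-in-pK plus learned correction.

#' Physical constants for score conversion
#'
#' @param R gas constant, kcal/(mol K); default 1.9872e-3.
#' @param T temperature, K; default 295.
#' @param c0 standard concentration implicit in pK, mol/l.
#' @return an object of class `physical_constants`.
#' @export
physical_constants <- function(R = 1.9872e-3, T = 295, c0 = 1) {
  stopifnot(T > 0, R > 0)
  structure(list(R = R, T = T, c0 = c0), class = "physical_constants")
}

#' Convert a docking score (kcal/mol) to pK units
#'
#' `pK = -log10(exp(S / RT)) = -S / (R T ln 10)`: linear and strictly
#' decreasing in `S`, so favourable (negative) scores map to positive pK.
#'
#' @param S docking score(s), kcal/mol.
#' @param constants a [physical_constants()]; default T = 295 K.
#' @return pK value(s).
#' @export
vina_to_pk <- function(S, constants = physical_constants()) {
  if (any(!is.finite(S))) stop("non-finite docking score")
  -S / (constants$R * constants$T * log(10))
}

#' Residual targets for delta-learning
#'
#' The regression target of the correction network is
#' `pk_exp - vina_to_pk(S)`; architecture and training loop are unchanged.
#'
#' @param pk_exp experimental affinities, pK units.
#' @param S baseline docking scores, kcal/mol.
#' @param ids optional identifiers used in error messages.
#' @param constants a [physical_constants()].
#' @return numeric vector of residuals, pK units.
#' @export
delta_train_targets <- function(pk_exp, S, ids = NULL,
                                constants = physical_constants()) {
  stopifnot(length(pk_exp) == length(S))
  if (anyNA(S)) {
    bad <- if (is.null(ids)) which(is.na(S)) else ids[is.na(S)]
    stop("missing baseline score for: ", paste(bad, collapse = ", "))
  }
  if (anyNA(pk_exp)) stop("missing experimental pK")
  pk_exp - vina_to_pk(S, constants)
}

#' Combined delta-learning prediction
#'
#' Total score = baseline converted to pK + learned correction.
#'
#' @param model a trained correction `aev_model` (or `aev_ensemble`).
#' @param system an [atomic_system()].
#' @param S baseline docking score, kcal/mol.
#' @param constants a [physical_constants()].
#' @return list of class `delta_prediction` with `S_pk`, `delta`, `total`
#'   (all pK units) and `std` (ensemble spread of the correction, `NA` for a
#'   single model).
#' @export
delta_predict <- function(model, system, S,
                          constants = physical_constants()) {
  pred <- predict_system(model, system)
  s_pk <- vina_to_pk(S, constants)
  structure(list(S_pk = s_pk, delta = pred$pk, total = s_pk + pred$pk,
                 std = pred$std,
                 atomic_contributions = pred$atomic_contributions),
            class = "delta_prediction")
}

#' @export
print.delta_prediction <- function(x, ...) {
  cat(sprintf("delta prediction: baseline %.3f + correction %.3f = %.3f pK\n",
              x$S_pk, x$delta, x$total))
  invisible(x)
}
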