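# Local observability of the P-Z-F-O model from DO-only measurements.
#
# The observation function is h(X) = O. Successive Lie derivatives of h
# along the model vector field f are built symbolically (stats::D on the
# model expressions), so gradient rows of any order are exact; temperature
# is held fixed during differentiation (Osat constant with respect to X).

.lie_cache <- new.env(parent = emptyenv())

# Symbolic right-hand side of the model, as a list of R expressions in
# P, Z, F, O and the parameter names (Osat enters as a frozen symbol).
.model_exprs <- function() {
  list(
    P = quote(rP * P * (1 - P / K) - gZ * P * Z / (hP + P) - mP * P),
    Z = quote(eZ * gZ * P * Z / (hP + P) - gF * Z * F / (hZ + Z) - mZ * Z),
    F = quote(eF * gF * Z * F / (hZ + Z) - mF * F),
    O = quote(aP * P - bR * (P + Z + F) + k2 * (Osat - O))
  )
}

# Lie derivative of a symbolic scalar along the model field:
# L_f expr = sum_i (d expr / d x_i) * f_i, built as an unevaluated call.
.lie_step <- function(expr, f) {
  vars <- c("P", "Z", "F", "O")
  terms <- lapply(seq_along(vars), function(i)
    call("*", call("(", stats::D(expr, vars[i])), call("(", f[[i]])))
  Reduce(function(a, b) call("+", a, b), terms)
}

# Symbolic gradient rows of L_f^k h for k = 0..order, cached per order.
.lie_gradient_exprs <- function(order) {
  key <- paste0("ord", order)
  if (!is.null(.lie_cache[[key]])) return(.lie_cache[[key]])
  f <- .model_exprs()
  vars <- c("P", "Z", "F", "O")
  L <- quote(O)
  rows <- list(lapply(vars, function(v) stats::D(L, v)))
  for (k in seq_len(order)) {
    L <- .lie_step(L, f)
    rows[[k + 1L]] <- lapply(vars, function(v) stats::D(L, v))
  }
  .lie_cache[[key]] <- rows
  rows
}

#' Gradient rows of successive Lie derivatives of the DO observation
#'
#' Row `k+1` is the state gradient of the k-th Lie derivative of `h(X) = O`
#' along the model field: row 1 is `[0, 0, 0, 1]`, row 2 the gradient of the
#' oxygen balance `dO/dt`, and higher rows are obtained by exact symbolic
#' differentiation of the composed dynamics (no finite differences).
#'
#' @param x Evaluation state `[P, Z, F, O]`.
#' @param params An [ecosystem_params()] object.
#' @param temp_c Water temperature, degrees C (frozen during
#'   differentiation).
#' @param order Highest Lie-derivative order, 1--3.
#' @return Numeric matrix with `order + 1` rows and 4 columns
#'   (`P`, `Z`, `F`, `O`).
#' @export
lie_gradients <- function(x, params, temp_c, order = 3L) {
  stopifnot(inherits(params, "ecosystem_params"), order %in% 1:3)
  validate_state(x)
  env <- list2env(c(as.list(params),
                    list(P = x[[1]], Z = x[[2]], F = x[[3]], O = x[[4]],
                         Osat = oxygen_saturation(temp_c, params$Osat_base))))
  rows <- .lie_gradient_exprs(as.integer(order))
  G <- t(vapply(rows, function(r)
    vapply(r, function(e) eval(e, env), numeric(1)), numeric(4)))
  dimnames(G) <- list(paste0("grad_Lf", 0:order, "h"), c("P", "Z", "F", "O"))
  G
}

#' Numerical rank of the local observability matrix
#'
#' Stacks the Lie-derivative gradient rows up to the requested order and
#' computes the numerical rank from singular values (relative cutoff
#' `tol * max(singular value)`). A rank of at least 3 at a non-equilibrium
#' state means phytoplankton and zooplankton biomass can be reconstructed
#' from the DO time series alone; the fourth direction (fish) is much less
#' sensitive.
#'
#' @inheritParams lie_gradients
#' @param tol Relative singular-value tolerance (> 0, default 1e-8).
#' @return An `observability_report`: list with the evaluation `state`,
#'   `gradients`, `singular_values`, `rank` and `F_sensitivity` (ratio of
#'   the F-column to the P-column norm).
#' @export
observability_rank <- function(x, params, temp_c, tol = 1e-8, order = 3L) {
  if (tol <= 0) stop("tol must be > 0")
  G <- lie_gradients(x, params, temp_c, order)
  sv <- svd(G, nu = 0, nv = 0)$d
  rank <- sum(sv > tol * max(sv))
  structure(list(state = c(P = x[[1]], Z = x[[2]], F = x[[3]], O = x[[4]]),
                 temp_c = temp_c, order = as.integer(order),
                 gradients = G, singular_values = sv, rank = rank,
                 F_sensitivity = f_sensitivity(x, params, temp_c, order)),
            class = "observability_report")
}

#' @export
print.observability_report <- function(x, ...) {
  cat("Local observability at state [",
      paste(signif(x$state, 4), collapse = ", "), "], T =",
      x$temp_c, "C\n")
  cat("rank:", x$rank, "of 4; singular values:",
      paste(signif(x$singular_values, 4), collapse = ", "), "\n")
  cat("F-sensitivity (||F col|| / ||P col||):",
      signif(x$F_sensitivity, 4), "\n")
  invisible(x)
}

#' Relative sensitivity of the observations to fish biomass
#'
#' Norm of the fish column of the stacked Lie-derivative gradients divided
#' by the norm of the phytoplankton column. Values well below 1 express the
#' weak observability of fish biomass: F influences DO mostly through
#' higher-order dynamics.
#'
#' @inheritParams lie_gradients
#' @param ref Reference column (`"P"` or `"Z"`).
#' @return Scalar ratio.
#' @export
f_sensitivity <- function(x, params, temp_c, order = 3L, ref = "P") {
  G <- lie_gradients(x, params, temp_c, order)
  ref <- match.arg(ref, c("P", "Z"))
  den <- sqrt(sum(G[, ref]^2))
  if (den < 1e-300) stop("reference column has (near) zero norm; ratio undefined")
  sqrt(sum(G[, "F"]^2)) / den
}
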