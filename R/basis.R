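#' Orthonormal polynomial basis for model covariates
#'
#' The polynomial mixed models in this package are expressed on a shared,
#' explicitly serialized basis: each numeric covariate is standardized over
#' the analysis sample (centering value, scale value) and then expanded into
#' polynomial columns that are orthogonalized against the intercept and
#' against each other and scaled to unit norm. Coefficients on this basis
#' are therefore comparable across covariates, and a basis fitted on one
#' sample can be re-applied to new data using the stored coefficients
#' without refitting.
#'
#' @param data data frame holding the covariates.
#' @param degrees named integer vector: maximum polynomial degree per
#'   covariate, e.g. `c(age = 2, weight = 2)`.
#' @return an object of class `poly_basis`: a list with one element per
#'   covariate carrying `center`, `scale`, `degree` and the
#'   orthonormalization coefficient matrix `coef` (rows: monomials
#'   `1, v, ..., v^d` of the standardized covariate; columns: basis columns
#'   of degree `1..d`).
#' @seealso [apply_basis()], [basis_to_json()]
#' @export
build_basis <- function(data, degrees) {
  stopifnot(is.data.frame(data), length(degrees) > 0, !is.null(names(degrees)))
  out <- list()
  for (v in names(degrees)) {
    x <- data[[v]]
    if (is.null(x)) stop("covariate `", v, "` not found in data")
    if (!is.numeric(x) || anyNA(x)) stop("covariate `", v, "` must be numeric without NA")
    d <- as.integer(degrees[[v]])
    s <- stats::sd(x)
    if (d >= 1L && (!is.finite(s) || s == 0)) {
      stop("covariate `", v, "` is constant; cannot build degree >= 1 basis")
    }
    z <- (x - mean(x)) / s
    V <- cbind(1, stats::poly(z, degree = d, raw = TRUE, simple = TRUE))
    qrd <- qr(V)
    if (qrd$rank < ncol(V)) stop("covariate `", v, "` gives a rank-deficient polynomial basis")
    Q <- qr.Q(qrd)
    R <- qr.R(qrd)
    # sign convention: each column positively correlated with its monomial
    sgn <- sign(diag(R))
    coef <- backsolve(R, diag(sgn))
    out[[v]] <- list(center = mean(x), scale = s, degree = d,
                     coef = coef[, -1L, drop = FALSE])
  }
  structure(out, class = "poly_basis")
}

#' Evaluate a stored basis on (new) data
#'
#' Uses the stored centering, scaling and orthonormalization coefficients;
#' nothing is refit, so columns have zero mean / unit norm / pairwise
#' orthogonality only on the sample the basis was built from.
#'
#' @param basis a `poly_basis`.
#' @param data data frame with the basis covariates.
#' @return data frame of basis columns named `<covariate>.<degree>`.
#' @export
apply_basis <- function(basis, data) {
  stopifnot(inherits(basis, "poly_basis"))
  cols <- list()
  for (v in names(basis)) {
    b <- basis[[v]]
    x <- data[[v]]
    if (is.null(x)) stop("covariate `", v, "` not found in data")
    z <- (x - b$center) / b$scale
    V <- cbind(1, stats::poly(z, degree = b$degree, raw = TRUE, simple = TRUE))
    U <- V %*% b$coef
    colnames(U) <- paste(v, seq_len(b$degree), sep = ".")
    cols[[v]] <- U
  }
  as.data.frame(do.call(cbind, cols))
}

#' Serialize a basis to JSON (and back)
#'
#' The basis definition travels with every simulated dataset so that the
#' generator and the fitter provably share one basis.
#'
#' @param basis a `poly_basis`.
#' @return `basis_to_json()`: a JSON string; `basis_from_json()`: a
#'   `poly_basis`.
#' @export
basis_to_json <- function(basis) {
  stopifnot(inherits(basis, "poly_basis"))
  ser <- lapply(unclass(basis), function(b) {
    list(center = b$center, scale = b$scale, degree = b$degree,
         coef = as.vector(b$coef))
  })
  jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA)
}

#' @rdname basis_to_json
#' @param json JSON string produced by [basis_to_json()].
#' @export
basis_from_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  out <- lapply(raw, function(b) {
    d <- as.integer(b$degree)
    list(center = b$center, scale = b$scale, degree = d,
         coef = matrix(b$coef, nrow = d + 1L, ncol = d))
  })
  structure(out, class = "poly_basis")
}
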