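#' Delay-differential model structures
#'
#' A DDA model relates the derivative of a series to monomials in its
#' delayed values,
#' \deqn{\dot x = \sum_{k=1}^K a_k \prod_{n=1}^N x(t-\tau_n)^{m_{n,k}},}
#' with at most `K = 3` monomials, `N <= 2` delays and per-monomial total
#' degree up to 3 (cubic nonlinearity). A model structure fixes the
#' monomials; the delay pair is set separately.
#'
#' @param terms list of integer exponent vectors, one per monomial; entry
#'   `n` of a vector is the order of delay embedding `n` in that monomial.
#' @param delays optional numeric vector of strictly positive delays in
#'   nucleotide steps (`tau1`, `tau2`, ...).
#' @return object of class `dda_model` with fields `terms`, `n_delays`,
#'   `delays` and a stable `id`.
#' @export
dda_model <- function(terms, delays = NULL) {
  if (length(terms) < 1L || length(terms) > 3L)
    stop("a model has 1 to 3 monomials")
  n_delays <- length(terms[[1L]])
  for (e in terms) {
    if (length(e) != n_delays || any(e < 0L) || any(e > 3L) || sum(e) < 1L ||
        sum(e) > 3L)
      stop("each monomial needs exponents in 0..3 with total degree 1..3")
  }
  terms <- lapply(terms, as.integer)
  if (anyDuplicated(vapply(terms, paste, character(1), collapse = ",")))
    stop("duplicate monomials are collinear and not allowed")
  terms <- terms[canonical_term_order(terms)]
  if (!is.null(delays)) {
    if (length(delays) != n_delays || any(delays < 1))
      stop("delays must be strictly positive, one per delay embedding")
    delays <- as.integer(delays)
  }
  structure(list(terms = terms, n_delays = n_delays, delays = delays,
                 id = model_id(terms)),
            class = "dda_model")
}

# canonical monomial order: total degree ascending, then earlier delay
# embeddings first (lexicographically descending exponents), matching
# the conventional a1 x_tau1 + a2 x_tau2 + a3 x_tau1 x_tau2 layout
canonical_term_order <- function(terms) {
  deg <- vapply(terms, sum, integer(1))
  lex <- vapply(terms, function(e)
    paste(sprintf("%02d", 3L - e), collapse = ""), character(1))
  order(deg, lex)
}

model_id <- function(terms) {
  paste(vapply(terms, function(e) {
    parts <- character(0)
    for (n in seq_along(e)) if (e[n] > 0L)
      parts <- c(parts, if (e[n] == 1L) sprintf("x%d", n)
                 else sprintf("x%d^%d", n, e[n]))
    paste(parts, collapse = "*")
  }, character(1)), collapse = " + ")
}

#' The default symmetric quadratic model
#'
#' `xdot = a1 x_tau1 + a2 x_tau2 + a3 x_tau1 x_tau2` — the simple,
#' symmetric model with only quadratic nonlinearity used for genomic
#' sequence data. Symmetry in the two delays halves the cost of a delay
#' sweep (unordered pairs only).
#'
#' @param tau1,tau2 delays in nucleotide steps; must satisfy
#'   `tau1 < tau2` (equal delays make the design collinear).
#' @return a `dda_model`.
#' @export
default_model <- function(tau1 = NULL, tau2 = NULL) {
  delays <- NULL
  if (!is.null(tau1) || !is.null(tau2)) {
    if (is.null(tau1) || is.null(tau2)) stop("supply both delays or none")
    if (tau1 >= tau2) stop("default symmetric model requires tau1 < tau2")
    delays <- c(tau1, tau2)
  }
  dda_model(list(c(1L, 0L), c(0L, 1L), c(1L, 1L)), delays = delays)
}

#' Set the delays of a model structure
#'
#' @param model a `dda_model`.
#' @param delays integer vector of delays, one per delay embedding.
#' @return the model with delays set.
#' @export
set_delays <- function(model, delays) {
  dda_model(model$terms, delays = delays)
}

#' Enumerate all DDA model structures
#'
#' All deduplicated models with up to `max_terms` distinct monomials in
#' `n_delays` delay embeddings, each monomial of total degree 1 to
#' `max_order`. With the defaults (3 terms, cubic, two delays) there are
#' 9 admissible monomials and 129 models; the default symmetric quadratic
#' model is among them.
#'
#' @param max_terms maximum number of monomials (default 3).
#' @param max_order maximum total degree per monomial (default 3).
#' @param n_delays number of delay embeddings (default 2).
#' @return named list of `dda_model` structures (delays unset), names =
#'   model ids.
#' @export
enumerate_models <- function(max_terms = 3L, max_order = 3L, n_delays = 2L) {
  stopifnot(max_terms >= 1L, max_terms <= 3L,
            max_order >= 1L, max_order <= 3L,
            n_delays >= 1L, n_delays <= 2L)
  grid <- expand.grid(rep(list(0:max_order), n_delays))
  deg <- rowSums(grid)
  keep <- deg >= 1L & deg <= max_order
  monomials <- lapply(which(keep), function(i) as.integer(grid[i, ]))
  # canonical order: total degree, then lexicographic on exponents
  ord <- order(vapply(monomials, sum, integer(1)),
               vapply(monomials, function(e) paste(e, collapse = ","),
                      character(1)))
  monomials <- monomials[ord]
  models <- list()
  for (k in seq_len(max_terms)) {
    for (idx in combn_list(length(monomials), k)) {
      m <- dda_model(monomials[idx])
      models[[m$id]] <- m
    }
  }
  models
}

# all k-subsets of 1..n as a list of integer vectors
combn_list <- function(n, k) {
  if (k > n) return(list())
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' @export
print.dda_model <- function(x, ...) {
  d <- if (is.null(x$delays)) "unset"
       else paste(x$delays, collapse = ", ")
  cat(sprintf("dda_model: xdot = %s   (delays: %s)\n", x$id, d))
  invisible(x)
}
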