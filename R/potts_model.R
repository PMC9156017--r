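#' Default 21-letter sequence alphabet
#'
#' The alphabet used throughout the package: the 20 standard amino acids in
#' alphabetical one-letter order followed by the alignment gap character
#' `"-"`, treated as an ordinary 21st state with no special semantics.
#'
#' @return Character vector of 21 distinct symbols.
#' @export
potts_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

#' Construct a Potts sequence model
#'
#' Bundles the pairwise coupling tensor `J` and the local field matrix `h`
#' that define a Potts Hamiltonian over `n` sites and `q` states, together
#' with the state alphabet and an optional native (starting) sequence. The
#' unnormalized log-probability of a sequence `a` is
#' \deqn{\sum_{i<j} J_{ij}(a_i, a_j) + \sum_i h_i(a_i).}
#'
#' The coupling tensor is stored fully symmetric: both the `(i, j)` and
#' `(j, i)` blocks are populated with `J[i, j, a, b] == J[j, i, b, a]`. Any
#' asymmetry in the input is averaged out at construction (with a warning if
#' it exceeds `1e-8`), and diagonal blocks `J[i, i, , ]` are forced to zero.
#'
#' @param J Numeric array of dimension `n x n x q x q`; `J[i, j, a, b]` is the
#'   coupling between state `a` at site `i` and state `b` at site `j`.
#' @param h Numeric matrix of dimension `n x q`; `h[i, a]` is the local field
#'   for state `a` at site `i`.
#' @param alphabet Character vector of `q` distinct state symbols. Defaults to
#'   [potts_alphabet()] when `q == 21`, otherwise to `s1, s2, ...` labels.
#' @param native_sequence Optional integer vector of length `n` with values in
#'   `1..q`: the reference starting sequence for simulations.
#' @return An object of class `"potts_model"` with elements `n_sites`,
#'   `n_states`, `J`, `h`, `alphabet`, `native_sequence`.
#' @export
potts_model <- function(J, h, alphabet = NULL, native_sequence = NULL) {
  if (!is.array(J) || length(dim(J)) != 4L)
    stop("J must be a 4-dimensional array (n x n x q x q)")
  if (!is.matrix(h))
    stop("h must be a matrix (n x q)")
  d <- dim(J)
  n <- d[1L]
  q <- d[3L]
  if (d[2L] != n || d[4L] != q)
    stop("J must have dimension n x n x q x q; got ", paste(d, collapse = " x "))
  if (nrow(h) != n || ncol(h) != q)
    stop("h must be ", n, " x ", q, " to match J")
  if (!all(is.finite(J)) || !all(is.finite(h)))
    stop("all entries of J and h must be finite")

  # symmetrize: J[i,j,a,b] <- (J[i,j,a,b] + J[j,i,b,a]) / 2
  Jt <- aperm(J, c(2L, 1L, 4L, 3L))
  asym <- max(abs(J - Jt))
  if (asym > 1e-8)
    warning("coupling tensor asymmetry of ", format(asym),
            " exceeds 1e-8; symmetrizing")
  J <- (J + Jt) / 2
  for (i in seq_len(n)) J[i, i, , ] <- 0

  if (is.null(alphabet)) {
    alphabet <- if (q == 21L) potts_alphabet() else paste0("s", seq_len(q))
  }
  if (length(alphabet) != q || anyDuplicated(alphabet))
    stop("alphabet must contain ", q, " distinct symbols")
  if (!is.null(native_sequence)) {
    native_sequence <- validate_sequence(native_sequence, n, q)
  }

  structure(
    list(n_sites = n, n_states = q, J = J, h = h,
         alphabet = as.character(alphabet),
         native_sequence = native_sequence),
    class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  nz <- sum(frobenius_coupling_map(x) > 0) / 2
  cat("Potts model:", x$n_sites, "sites,", x$n_states, "states\n")
  cat("  coupled site pairs:", nz, "of",
      x$n_sites * (x$n_sites - 1) / 2, "\n")
  cat("  native sequence:",
      if (is.null(x$native_sequence)) "none" else
        paste(x$alphabet[x$native_sequence], collapse = ""), "\n")
  invisible(x)
}

validate_sequence <- function(seq, n, q) {
  seq <- as.integer(seq)
  if (length(seq) != n)
    stop("sequence length ", length(seq), " does not match model size ", n)
  if (anyNA(seq) || any(seq < 1L) || any(seq > q))
    stop("sequence states must lie in 1..", q)
  seq
}

check_mode <- function(mode) {
  match.arg(toupper(mode), c("CE", "IE", "UE"))
}

mode_code <- function(mode) {
  match(check_mode(mode), c("CE", "IE", "UE")) - 1L
}

#' Hamiltonian log weight of a sequence
#'
#' Evaluates the exponent of the Potts probability,
#' \eqn{\sum_{i<j} J_{ij}(a_i, a_j) + \sum_i h_i(a_i)}: the log of the
#' unnormalized sequence probability (the partition function is never
#' computed).
#'
#' @param seq Integer vector of length `n_sites` with states in `1..q`.
#' @param model A [potts_model()].
#' @return A finite scalar.
#' @export
hamiltonian_log_weight <- function(seq, model) {
  stopifnot(inherits(model, "potts_model"))
  n <- model$n_sites
  seq <- validate_sequence(seq, n, model$n_states)
  hsum <- sum(model$h[cbind(seq_len(n), seq)])
  if (n < 2L) return(hsum)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  jsum <- sum(model$J[cbind(pr[, 1L], pr[, 2L], seq[pr[, 1L]], seq[pr[, 2L]])])
  jsum + hsum
}

#' Single-site Gibbs conditional distribution
#'
#' The probability of each of the `q` states at one site, conditional on the
#' residues at all other sites. Under `"CE"` the distribution is proportional
#' to \eqn{\exp(h_i(a) + \sum_{j \ne i} J_{ij}(a, a_j))}; under `"IE"` the
#' couplings are dropped (\eqn{\propto \exp(h_i(a))}); under `"UE"` it is
#' uniform. Computed in log space with max-subtraction.
#'
#' @inheritParams hamiltonian_log_weight
#' @param site Site index in `1..n_sites`.
#' @param mode One of `"CE"`, `"IE"`, `"UE"`.
#' @return Numeric vector of `q` probabilities summing to 1.
#' @export
conditional_distribution <- function(seq, site, model, mode = "CE") {
  stopifnot(inherits(model, "potts_model"))
  n <- model$n_sites
  q <- model$n_states
  mode <- check_mode(mode)
  site <- as.integer(site)
  if (length(site) != 1L || is.na(site) || site < 1L || site > n)
    stop("site must be a single index in 1..", n)
  if (mode == "UE") return(rep(1 / q, q))
  seq <- validate_sequence(seq, n, q)
  lw <- model$h[site, ]
  if (mode == "CE" && n > 1L) {
    # sum_j J[site, j, a, seq_j] for each state a, vectorized over (j, a)
    Jsite <- model$J[site, , , , drop = TRUE]
    dim(Jsite) <- c(n, q, q)
    idx <- cbind(rep(seq_len(n), times = q),
                 rep(seq_len(q), each = n),
                 rep(seq, times = q))
    lw <- lw + colSums(matrix(Jsite[idx], n, q))
  }
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Derive a nested model
#'
#' Returns the model restricted to an evolution regime: `"CE"` keeps the
#' parameters unchanged, `"IE"` zeroes all couplings (independent sites),
#' `"UE"` zeroes couplings and fields (uniform null).
#'
#' @inheritParams conditional_distribution
#' @return A [potts_model()].
#' @export
nest_model <- function(model, mode = "CE") {
  stopifnot(inherits(model, "potts_model"))
  mode <- check_mode(mode)
  if (mode %in% c("IE", "UE")) model$J[] <- 0
  if (mode == "UE") model$h[] <- 0
  model
}

#' Frobenius-norm coupling map
#'
#' Summarizes the coupling strength between every pair of sites as the
#' Frobenius norm of the corresponding `q x q` coupling block,
#' \eqn{\|J_{ij}\|_F = \sqrt{\sum_{a,b} J_{ij}(a,b)^2}}. The result is a
#' symmetric nonnegative matrix with zero diagonal, the standard
#' visualization of which site pairs interact.
#'
#' @inheritParams nest_model
#' @return An `n x n` numeric matrix.
#' @export
frobenius_coupling_map <- function(model) {
  stopifnot(inherits(model, "potts_model"))
  sqrt(apply(model$J^2, c(1L, 2L), sum))
}
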