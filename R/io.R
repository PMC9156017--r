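#' Write a Potts model to a portable JSON container
#'
#' Serializes the model to a single JSON file: a header with the number of
#' sites and states, the alphabet and the native sequence, plus the full
#' field matrix and coupling tensor (flattened column-major with recorded
#' dimensions). Numbers are written at full precision, so a round trip
#' through [read_potts_model()] is exact.
#'
#' @param model A [potts_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_potts_model <- function(model, path) {
  stopifnot(inherits(model, "potts_model"))
  obj <- list(
    container = "potts_model",
    n_sites = model$n_sites, n_states = model$n_states,
    alphabet = model$alphabet,
    native_sequence = model$native_sequence,
    h = list(dim = dim(model$h), values = as.vector(model$h)),
    J = list(dim = dim(model$J), values = as.vector(model$J)))
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a Potts model from its JSON container
#'
#' @param path File written by [write_potts_model()].
#' @return A [potts_model()].
#' @export
read_potts_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "potts_model"))
    stop("not a potts_model container: ", path)
  J <- array(obj$J$values, dim = obj$J$dim)
  h <- matrix(obj$h$values, obj$h$dim[1L], obj$h$dim[2L])
  native <- obj$native_sequence
  if (length(native) == 0) native <- NULL
  potts_model(J, h, alphabet = obj$alphabet, native_sequence = native)
}

#' Export sequences as FASTA
#'
#' Translates integer state vectors through the model alphabet and writes
#' them as an uncompressed FASTA file (gap states become `"-"` characters).
#'
#' @param seqs A single integer sequence or a list of them.
#' @param alphabet Character vector mapping state indices to symbols, e.g.
#'   `model$alphabet`.
#' @param path Output FASTA path.
#' @param names Sequence names; defaults to `seq_1, seq_2, ...`.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(seqs, alphabet, path, names = NULL) {
  if (!is.list(seqs)) seqs <- list(seqs)
  if (is.null(names)) names <- paste0("seq_", seq_along(seqs))
  stopifnot(length(names) == length(seqs))
  chars <- lapply(seqs, function(s) alphabet[s])
  seqinr::write.fasta(chars, names = names, file.out = path)
  invisible(path)
}

#' Write an evolution trace as TSV
#'
#' One row per tracked generation (`generation`, `site`, `before`,
#' `proposed`, `accepted`), preceded by `#`-prefixed header lines carrying
#' the mode, seeds and protocol parameters.
#'
#' @param trace An `evolution_trace`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "evolution_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# mode: ", trace$mode),
    paste0("# n_sites: ", trace$n_sites),
    paste0("# total_generations: ", trace$total_generations),
    paste0("# burn_in: ", trace$burn_in),
    paste0("# site_seed: ", trace$site_seed),
    paste0("# residue_seed: ", trace$residue_seed),
    paste0("# reference_sequence: ",
           paste(trace$reference_sequence, collapse = ","))), con)
  utils::write.table(
    data.frame(generation = seq_along(trace$site), site = trace$site,
               before = trace$before, proposed = trace$proposed,
               accepted = as.integer(trace$accepted)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an I-site curve as tidy TSV
#'
#' Long format: one row per generation and statistic with the mean, standard
#' deviation and replicate count, ready for plotting or joining across
#' modes.
#'
#' @param curve An [isite_curve()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_isite_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "isite_curve"))
  df <- rbind(
    data.frame(generation = curve$generation, mode = curve$mode,
               statistic = "I_all", mean = curve$i_all_mean,
               sd = curve$i_all_sd, n_replicates = curve$n_replicates),
    data.frame(generation = curve$generation, mode = curve$mode,
               statistic = "I_adj", mean = curve$i_adj_mean,
               sd = curve$i_adj_sd, n_replicates = curve$n_replicates))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
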