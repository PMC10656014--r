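# File interfaces: FASTA / peptide lists in, reads and predictions as TSV,
# and the YAML run configuration.

#' Read protein sequences from FASTA
#'
#' @param path Multi-record FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
read_fasta_proteins <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("FASTA file has no records: ", path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Read a plain peptide list (one peptide per line)
#'
#' @param path Text file, one amino-acid string per line; blank lines ignored.
#' @return Character vector of peptides.
#' @export
read_peptide_list <- function(path) {
  if (!file.exists(path)) stop("peptide list not found: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write / read simulated reads as TSV
#'
#' Columns: `read_id`, then intensities `t{t}_c{i}` in cycle-major order
#' (cycle `t` from 0, color `i` within), then `true_peptide_id` when known.
#' Values round-trip at full double precision.
#'
#' @param reads A `pb_reads` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  stopifnot(inherits(reads, "pb_reads"))
  d <- dim(reads$intensities)
  n <- d[1]; nd <- d[2]; nt <- d[3]
  cols <- lapply(seq_len(nt) - 1L, function(t)
    lapply(seq_len(nd) - 1L, function(i) reads$intensities[, i + 1L, t + 1L]))
  flat <- do.call(cbind, lapply(unlist(cols, recursive = FALSE), identity))
  colnames(flat) <- as.vector(vapply(seq_len(nt) - 1L, function(t)
    paste0("t", t, "_c", seq_len(nd) - 1L), character(nd)))
  df <- data.frame(read_id = reads$read_id)
  for (j in seq_len(ncol(flat)))
    df[[colnames(flat)[j]]] <- sprintf("%.17g", flat[, j])
  if (!is.null(reads$true_peptide)) df$true_peptide_id <- reads$true_peptide
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @param n_colors Number of colors expected in the file.
#' @export
read_reads_tsv <- function(path, n_colors) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  icols <- grep("^t[0-9]+_c[0-9]+$", names(df), value = TRUE)
  nt <- length(icols) / n_colors
  stopifnot(nt == as.integer(nt))
  arr <- array(0, c(nrow(df), n_colors, nt))
  for (t in seq_len(nt) - 1L)
    for (i in seq_len(n_colors) - 1L)
      arr[, i + 1L, t + 1L] <- as.numeric(df[[paste0("t", t, "_c", i)]])
  structure(list(intensities = arr,
                 true_peptide = df$true_peptide_id,
                 read_id = df$read_id,
                 n_dropped = NA_integer_),
            class = "pb_reads")
}

#' Run configuration file (YAML)
#'
#' A config carries the model parameters, the labeling scheme (a list of
#' per-color letter sets) and a seed; [read_config()] and [write_config()]
#' round-trip losslessly.
#'
#' @param params A [probeam_params()].
#' @param scheme A [label_scheme()].
#' @param seed Integer seed.
#' @return For `read_config`, a list with `params`, `scheme`, `seed`.
#' @export
write_config <- function(path, params, scheme, seed = 1L) {
  nd <- attr(scheme, "n_colors")
  colors <- lapply(seq_len(nd) - 1L, function(i) as.list(names(scheme)[scheme == i]))
  yaml::write_yaml(list(params = unclass(params)[setdiff(names(params), "n_colors")],
                        colors = colors, seed = as.integer(seed)), path)
  invisible(path)
}

#' @rdname write_config
#' @param path Config file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  scheme <- label_scheme(lapply(y$colors, unlist))
  p <- y$params
  params <- probeam_params(n_colors = attr(scheme, "n_colors"),
                           n_cycles = p$n_cycles,
                           e = p$e, l = p$l, m = p$m, p_d = p$p_d,
                           mu = p$mu, sigma = p$sigma, sigma_b = p$sigma_b,
                           h = p$h, n_beam = p$n_beam)
  list(params = params, scheme = scheme, seed = as.integer(y$seed))
}

#' Write the digest table (peptide, dye sequence, priors) as TSV
#'
#' @param db A [build_database()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_digest_tsv <- function(db, path) {
  df <- data.frame(peptide = db$peptides$sequence,
                   dye_seq = db$peptides$dye_seq,
                   P_P = sprintf("%.17g", db$prior_p),
                   P_D = sprintf("%.17g",
                                 db$dye_seqs$prior[db$peptides$dseq_id]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$peptide), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
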