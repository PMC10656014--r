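# The beam recursion: propagate each kept state through the one-cycle
# transition model, weight by the observation, merge duplicate successors
# across predecessors (log-sum-exp), renormalize and truncate to the N_B
# highest-weight states.

#' One beam recursion step
#'
#' @param db A [build_database()] result.
#' @param beam A `pb_beam` (from [greedy_initial_beam()] or a previous step).
#' @param x_t Intensity vector observed after this cycle.
#' @param params A [probeam_params()].
#' @return The updated, renormalized `pb_beam` of at most `n_beam` states.
#'   Errors if every successor was pruned away (undecodable read).
#' @export
beam_step <- function(db, beam, x_t, params) {
  stopifnot(inherits(beam, "pb_beam"), length(x_t) == params$n_colors)
  r <- pb_beam_step(db_ptr(db), lapply(beam$states, unclass), beam$logw,
                    as.numeric(x_t), unclass(params))
  if (isTRUE(r$empty))
    stop("undecodable read: every successor state was pruned away")
  structure(list(states = lapply(r$states, function(s) {
    class(s) <- "pb_state"
    s
  }), logw = r$logw, pruned = isTRUE(r$pruned), t = beam$t + 1L),
  class = "pb_beam")
}

#' Decode one read with the beam decoder
#'
#' Initializes the beam from the first observation with
#' [greedy_initial_beam()], applies [beam_step()] for each Edman cycle, and
#' marginalizes the final beam into a peptide posterior:
#' `P(p | X) = sum_s zeta(s) P(p | s)`.
#'
#' @param db A [build_database()] result.
#' @param read Intensity matrix, `n_colors` rows by `n_cycles + 1` columns.
#' @param params A [probeam_params()].
#' @param top_k How many ranked candidates to report.
#' @return A `pb_decode`: `peptide_id`, `sequence` and `posterior` of the MAP
#'   peptide, a `ranked` data.frame of the top candidates, the full
#'   `posterior` vector, and flags `pruned` (some dye-loss mass was
#'   discarded) and `undecodable` (no prediction; all successors pruned).
#' @export
decode_read <- function(db, read, params, top_k = 2L) {
  read <- as.matrix(read)
  stopifnot(nrow(read) == params$n_colors,
            ncol(read) == params$n_cycles + 1L)
  r <- pb_decode_read(db_ptr(db), read, unclass(params))
  decode_result(db, r$posterior, isTRUE(r$pruned), isTRUE(r$undecodable), top_k)
}

decode_result <- function(db, post, pruned, undecodable, top_k) {
  if (undecodable) {
    return(structure(list(peptide_id = NA_integer_, sequence = NA_character_,
                          posterior = NA_real_, ranked = NULL,
                          posterior_all = NULL, pruned = pruned,
                          undecodable = TRUE), class = "pb_decode"))
  }
  ord <- order(-post, db$peptides$id)
  k <- min(top_k, length(post))
  ranked <- data.frame(peptide_id = db$peptides$id[ord[seq_len(k)]],
                       sequence = db$peptides$sequence[ord[seq_len(k)]],
                       posterior = post[ord[seq_len(k)]])
  structure(list(peptide_id = ranked$peptide_id[1],
                 sequence = ranked$sequence[1],
                 posterior = ranked$posterior[1],
                 ranked = ranked, posterior_all = post,
                 pruned = pruned, undecodable = FALSE),
            class = "pb_decode")
}

#' @export
print.pb_decode <- function(x, ...) {
  if (x$undecodable) {
    cat("undecodable read (all successors pruned)\n")
  } else {
    cat(sprintf("MAP peptide %d (%s), posterior %.4f%s\n", x$peptide_id,
                x$sequence, x$posterior, if (x$pruned) " [pruned]" else ""))
  }
  invisible(x)
}

#' Decode a batch of reads
#'
#' Maps the beam decoder over a read set in input order (single-threaded,
#' deterministic).  Undecodable reads are flagged, not fatal.
#'
#' @param db A [build_database()] result.
#' @param reads A `pb_reads` object from [simulate_reads()] /
#'   [read_reads_tsv()], or a 3-d array `[read, color, cycle]`.
#' @param params A [probeam_params()].
#' @return A data.frame with one row per read: `read_id`,
#'   `predicted_peptide_id`, `peptide_sequence`, `posterior`, the rank-2
#'   candidate and its posterior, and flags `pruned` / `undecodable`.  The
#'   full posterior matrix (reads by peptides) is attached as attribute
#'   `"posterior"`.
#' @export
decode_batch <- function(db, reads, params) {
  arr <- if (inherits(reads, "pb_reads")) reads$intensities else reads
  stopifnot(length(dim(arr)) == 3L, dim(arr)[2] == params$n_colors,
            dim(arr)[3] == params$n_cycles + 1L)
  r <- pb_decode_batch(db_ptr(db), arr, unclass(params))
  post <- r$posterior
  n <- nrow(post)
  pred <- max.col(replace(post, is.na(post), -Inf), ties.method = "first")
  # rank-2 candidate
  second <- if (ncol(post) >= 2L) {
    tmp <- replace(post, is.na(post), -Inf)
    tmp[cbind(seq_len(n), pred)] <- -Inf
    max.col(tmp, ties.method = "first")
  } else rep(NA_integer_, n)
  undec <- as.logical(r$undecodable)
  out <- data.frame(
    read_id = if (inherits(reads, "pb_reads")) reads$read_id else seq_len(n),
    predicted_peptide_id = ifelse(undec, NA_integer_, pred),
    peptide_sequence = ifelse(undec, NA_character_, db$peptides$sequence[pred]),
    posterior = ifelse(undec, NA_real_, post[cbind(seq_len(n), pred)]),
    runner_up_id = ifelse(undec, NA_integer_, second),
    runner_up_posterior = ifelse(undec | is.na(second), NA_real_,
                                 post[cbind(seq_len(n), second)]),
    pruned = as.logical(r$pruned),
    undecodable = undec,
    stringsAsFactors = FALSE
  )
  attr(out, "posterior") <- post
  out
}

#' Write predictions as TSV
#'
#' @param predictions A [decode_batch()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
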