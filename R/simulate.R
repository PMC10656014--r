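# Generative read simulator, matched one-to-one to the decoder's model:
# uniform peptide choice, per-fluorophore dye miss before the first
# observation, then per cycle detachment -> per-fluorophore dye loss ->
# Edman removal, with Gaussian emissions after each stage.  Once a read
# carries no attached fluorophore it only emits background noise (absorbing,
# exactly as the decoder assumes).

#' Simulate fluorosequencing reads
#'
#' Draws a peptide uniformly, applies dye miss (rate `m`) to each ideal
#' fluorophore, and emits `x_0`.  Each Edman cycle then applies, in order:
#' whole-peptide detachment (`p_d`, permanently zeroing the attached counts),
#' independent per-fluorophore dye loss (`l`), and Edman removal (success
#' `1 - e`) of the next dye-sequence symbol -- removing the attached dye with
#' probability `K_i / N_i` when a residue of color `i` goes -- followed by a
#' Gaussian emission.  Reads that start with no attached dye are dropped (not
#' regenerated) and counted in `n_dropped`.
#'
#' @param db A [build_database()] result.
#' @param params A [probeam_params()].
#' @param n_reads Number of reads to generate before dark-start filtering.
#' @param seed Optional integer seed.
#' @return A `pb_reads`: `intensities` (array `[read, color, cycle]` with
#'   `n_cycles + 1` cycle slices), `true_peptide` (generating peptide ids),
#'   `read_id`, and `n_dropped`.
#' @export
simulate_reads <- function(db, params, n_reads, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_reads >= 0)
  nd <- params$n_colors
  nc <- params$n_cycles
  n <- as.integer(n_reads)

  pep <- sample.int(nrow(db$peptides), n, replace = TRUE, prob = db$prior_p)
  dseq <- db$peptides$dye_seq[pep]
  len <- nchar(dseq)
  maxlen <- max(len, 1L)
  # symbol matrix: reads x positions, "." padded past the trimmed end
  sym <- matrix(".", n, maxlen)
  for (jj in seq_len(maxlen)) {
    has <- len >= jj
    sym[has, jj] <- substr(dseq[has], jj, jj)
  }
  dct <- matrix(0L, nrow(db$dye_seqs), nd)
  for (j in seq_len(nrow(db$dye_seqs)))
    dct[j, ] <- dye_count(db$dye_seqs$dye_seq[j], nd)
  N <- dct[db$peptides$dseq_id[pep], , drop = FALSE]

  X <- array(0, c(n, nd, nc + 1L))
  K <- matrix(0L, n, nd)
  for (i in seq_len(nd))
    K[, i] <- rbinom(n, N[, i], 1 - params$m)
  emit <- function(K) {
    matrix(rnorm(n * nd, mean = as.vector(K) * params$mu,
                 sd = sigma_eff(as.vector(K), params)), n, nd)
  }
  X[, , 1] <- emit(K)
  keep <- rowSums(K) > 0L

  pos <- rep.int(0L, n) # removed-symbol count
  for (t in seq_len(nc)) {
    active <- rowSums(K) > 0L
    det <- active & runif(n) < params$p_d
    K[det, ] <- 0L
    surv <- active & !det
    for (i in seq_len(nd))
      K[surv, i] <- rbinom(sum(surv), K[surv, i], 1 - params$l)
    edman <- surv & rowSums(K) > 0L & runif(n) < (1 - params$e)
    if (any(edman)) {
      idx <- which(edman)
      s <- sym[cbind(idx, pos[idx] + 1L)]
      for (i in seq_len(nd) - 1L) {
        ci <- idx[s == as.character(i)]
        if (length(ci)) {
          take <- runif(length(ci)) < K[ci, i + 1L] / N[ci, i + 1L]
          K[ci[take], i + 1L] <- K[ci[take], i + 1L] - 1L
          N[ci, i + 1L] <- N[ci, i + 1L] - 1L
        }
      }
      pos[idx] <- pos[idx] + 1L
    }
    X[, , t + 1L] <- emit(K)
  }

  structure(list(intensities = X[keep, , , drop = FALSE],
                 true_peptide = pep[keep],
                 read_id = seq_len(sum(keep)),
                 n_dropped = sum(!keep)),
            class = "pb_reads")
}

#' @export
print.pb_reads <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("%d read(s), %d color(s) x %d observation(s); %d dark read(s) dropped\n",
              d[1], d[2], d[3], x$n_dropped))
  invisible(x)
}

#' Random peptide database for experiments
#'
#' Uniform random amino-acid strings over the 20 standard residues, labeled
#' with `scheme`, deduplicated; only peptides with at least one labelable
#' residue are retained, and generation continues until `n_peptides` such
#' peptides exist.
#'
#' @param n_peptides Number of retained peptides.
#' @param length_range Integer range of peptide lengths (inclusive).
#' @param scheme A [label_scheme()].
#' @param seed Optional integer seed.
#' @return A `pb_database`.
#' @export
make_random_database <- function(n_peptides, length_range = c(6L, 12L),
                                 scheme, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_peptides >= 1L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[1] <= length_range[2])
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!any(names(scheme) %in% aa))
    stop("the labeling scheme covers no standard amino acid")
  got <- character(0)
  tries <- 0L
  while (length(got) < n_peptides) {
    tries <- tries + 1L
    if (tries > 1000L * n_peptides)
      stop("could not generate enough labelable peptides")
    lens <- sample(seq.int(length_range[1], length_range[2]),
                   n_peptides, replace = TRUE)
    cand <- vapply(lens, function(l)
      paste(sample(aa, l, replace = TRUE), collapse = ""), character(1))
    lab <- vapply(cand, function(p) nzchar(to_dye_sequence(p, scheme)),
                  logical(1))
    got <- unique(c(got, cand[lab]))
  }
  suppressMessages(build_database(got[seq_len(n_peptides)], scheme))
}
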