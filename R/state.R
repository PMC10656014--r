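#' Decoder state (N, K, R)
#'
#' A state is the triple of `N` (remaining labelable residues per color),
#' `K` (remaining attached fluorophores per color, `0 <= K <= N`
#' componentwise) and `R` (the removed dye-sequence prefix).  A detached
#' peptide is encoded as `K = 0`.  States are value-equal on the triple;
#' [state_key()] gives the canonical serialization used for hashing, merging
#' and deterministic tie-breaks.
#'
#' @param N,K Integer vectors of equal length (one entry per color).
#' @param R Removed-prefix string over color digits and `"."`.
#' @return A `pb_state`.
#' @examples
#' pb_state(N = c(3, 0, 2), K = c(1, 0, 1), R = "..")
#' @export
pb_state <- function(N, K, R = "") {
  N <- as.integer(N)
  K <- as.integer(K)
  stopifnot(length(N) == length(K), length(N) >= 1L,
            is.character(R), length(R) == 1L)
  if (any(N < 0) || any(K < 0) || any(K > N))
    stop("state requires 0 <= K <= N componentwise")
  if (nzchar(R) && grepl("[^0-9.]", R))
    stop("R must be over color digits and '.'")
  structure(list(N = N, K = K, R = R), class = "pb_state")
}

#' @export
print.pb_state <- function(x, ...) {
  cat(sprintf("state N=[%s] K=[%s] R=\"%s\"\n",
              paste(x$N, collapse = ","), paste(x$K, collapse = ","), x$R))
  invisible(x)
}

#' @rdname pb_state
#' @param s A `pb_state`.
#' @export
state_key <- function(s) {
  paste0(s$R, "|", paste(s$N, collapse = ","), "|", paste(s$K, collapse = ","))
}

#' Dye sequences consistent with a state
#'
#' Returns every database dye sequence that starts with the removed prefix
#' `R` and whose remaining suffix has per-color counts equal to `N`.  Served
#' by the prefix index built over the database (one entry per (prefix,
#' remainder-count) pair), not by scanning.
#'
#' @param db A [build_database()] result.
#' @param N Integer count vector (length `n_colors`).
#' @param R Removed-prefix string.
#' @return Character vector of dye sequences (possibly empty), with the
#'   matching `db$dye_seqs$id` values as the `ids` attribute.
#' @export
eta_members <- function(db, N, R = "") {
  ids <- pb_eta(db_ptr(db), as.integer(N), R)
  structure(db$dye_seqs$dye_seq[ids], ids = ids)
}

#' Peptide distribution conditional on a state
#'
#' The peptides compatible with state `s` are those whose dye sequence lies
#' in `eta(s.N, s.R)`; within that set the posterior is the renormalized
#' prior, independent of the observation history.
#'
#' @param db A [build_database()] result.
#' @param s A [pb_state()].
#' @return Named numeric vector of probabilities over compatible peptide ids;
#'   sums to 1.
#' @export
peptide_given_state <- function(db, s) {
  ids <- attr(eta_members(db, s$N, s$R), "ids")
  if (length(ids) == 0L)
    stop("inconsistent state: no dye sequence matches (N, R)")
  sel <- db$peptides$dseq_id %in% ids
  p <- db$prior_p[sel]
  stats::setNames(p / sum(p), db$peptides$id[sel])
}

#' Elementary state edits
#'
#' `detach()` zeroes all attached fluorophores (idempotent).  `dec_K()` and
#' `dec_N()` decrement one color's attached / remaining count.
#' `append_removed()` appends one removed symbol to `R`.  Colors are 0-based,
#' matching the dye-sequence digits.
#'
#' @param s A [pb_state()].
#' @param i 0-based color index.
#' @param a Removed symbol: a color digit or `"."`.
#' @return The edited `pb_state`.
#' @name state-edits
NULL

#' @rdname state-edits
#' @export
detach <- function(s) {
  s$K <- rep.int(0L, length(s$K))
  s
}

#' @rdname state-edits
#' @export
dec_K <- function(s, i) {
  j <- i + 1L
  if (j < 1L || j > length(s$K) || s$K[j] < 1L)
    stop("dec_K requires K_i >= 1")
  s$K[j] <- s$K[j] - 1L
  s
}

#' @rdname state-edits
#' @export
dec_N <- function(s, i) {
  j <- i + 1L
  if (j < 1L || j > length(s$N) || s$N[j] < 1L)
    stop("dec_N requires N_i >= 1")
  # K <= N may be violated transiently inside the dye-attached removal
  # combination dec_K(dec_N(...)); the combination restores it
  s$N[j] <- s$N[j] - 1L
  s
}

#' @rdname state-edits
#' @export
append_removed <- function(s, a) {
  stopifnot(is.character(a), length(a) == 1L, nchar(a) == 1L)
  if (!grepl("^[0-9.]$", a)) stop("removed symbol must be a color digit or '.'")
  s$R <- paste0(s$R, a)
  s
}

#' Removability indicator
#'
#' 1 when dye sequence `d` starts with prefix `r` and the character of `d`
#' just after `r` equals `a`.  Past the end of a (trimmed) dye sequence the
#' next character is defined to be `"."`: everything beyond the last labeled
#' residue is unlabeled.
#'
#' @param r Removed-prefix string.
#' @param d Dye-sequence string.
#' @param a Candidate removed symbol (color digit or `"."`).
#' @return 1L or 0L.
#' @export
alpha_removal <- function(r, d, a) {
  ok <- if (nchar(r) >= nchar(d)) substr(r, 1L, nchar(d)) == d else startsWith(d, r)
  if (!ok) return(0L)
  nxt <- if (nchar(r) >= nchar(d)) "." else substr(d, nchar(r) + 1L, nchar(r) + 1L)
  as.integer(nxt == a)
}
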