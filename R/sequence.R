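#' Labeling scheme: amino-acid letters to fluorophore colors
#'
#' A labeling scheme assigns each labelable amino-acid letter to a fluorophore
#' color index in `0 .. n_colors - 1`.  Several letters may share one color
#' (e.g. D and E labeled by the same fluorophore), but a letter maps to at
#' most one color.  Unmapped letters are unlabeled and render as `"."` in dye
#' sequences.
#'
#' @param colors A list of character vectors, one per color in color order,
#'   e.g. `list(c("D", "E"), "C", "Y")` for three colors.
#' @return A `pb_scheme`: a named integer vector (letter -> 0-based color)
#'   with an `n_colors` attribute.
#' @examples
#' label_scheme(list(c("D", "E"), "C", "Y"))
#' @export
label_scheme <- function(colors) {
  stopifnot(is.list(colors), length(colors) >= 1L)
  letters_ <- character(0)
  idx <- integer(0)
  for (i in seq_along(colors)) {
    set <- toupper(as.character(colors[[i]]))
    if (length(set) == 0L)
      stop("every declared color needs at least one amino-acid letter")
    if (any(nchar(set) != 1L) || any(!set %in% LETTERS))
      stop("amino acids must be single uppercase letters")
    letters_ <- c(letters_, set)
    idx <- c(idx, rep.int(i - 1L, length(set)))
  }
  if (anyDuplicated(letters_))
    stop("an amino-acid letter may map to at most one color")
  structure(stats::setNames(idx, letters_),
            n_colors = length(colors), class = "pb_scheme")
}

#' @export
print.pb_scheme <- function(x, ...) {
  nd <- attr(x, "n_colors")
  cat(sprintf("labeling scheme over %d color(s)\n", nd))
  for (i in seq_len(nd) - 1L)
    cat(sprintf("  color %d: %s\n", i, paste(names(x)[x == i], collapse = ", ")))
  invisible(x)
}

#' In silico tryptic digestion
#'
#' Cleaves C-terminal of K and R, except when the next residue is proline;
#' zero missed cleavages.  Fragments are returned in N-to-C order and their
#' concatenation equals the input.
#'
#' @param protein_sequence A single nonempty amino-acid string.
#' @return Character vector of peptide fragments.
#' @examples
#' digest_trypsin("AAKAA")  # "AAK" "AA"
#' digest_trypsin("AKPA")   # "AKPA": K before P is not cleaved
#' @export
digest_trypsin <- function(protein_sequence) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L)
  s <- toupper(protein_sequence)
  if (!nzchar(s)) stop("empty protein sequence")
  if (grepl("[^A-Z]", s)) stop("protein sequence contains non-letter characters")
  cuts <- gregexpr("(?<=[KR])(?!P)", s, perl = TRUE)[[1]]
  if (cuts[1] == -1L) return(s)
  cuts <- cuts[cuts <= nchar(s)]  # no empty trailing fragment
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, nchar(s))
  keep <- starts <= ends
  substring(s, starts[keep], ends[keep])
}

#' Dye-sequence representation of a peptide
#'
#' Each residue is replaced by the digit of the color its fluorophore carries,
#' or `"."` if unlabeled; trailing dots are trimmed because sequencing past
#' the last labeled residue is uninformative.  The result may be the empty
#' string when no residue is labelable.
#'
#' @param peptide Amino-acid string.
#' @param scheme A [label_scheme()].
#' @param n_colors Number of colors; defaults to the scheme's declaration.
#' @return A dye-sequence string over `{"0", ..., "."}`.
#' @examples
#' sch <- label_scheme(list(c("C", "E"), "K", "D"))
#' to_dye_sequence("DAREICIKS", sch)  # "2..0.0.1"
#' @export
to_dye_sequence <- function(peptide, scheme, n_colors = attr(scheme, "n_colors")) {
  stopifnot(inherits(scheme, "pb_scheme"))
  if (any(scheme >= n_colors)) stop("scheme color indices must be < n_colors")
  chars <- strsplit(toupper(peptide), "", fixed = TRUE)[[1]]
  out <- ifelse(chars %in% names(scheme),
                as.character(scheme[chars]), ".")
  d <- paste(out, collapse = "")
  sub("\\.+$", "", d)
}

#' Per-color dye counts of a dye sequence
#'
#' @param d Dye-sequence string.
#' @param n_colors Number of colors.
#' @return Integer vector of length `n_colors`; element `i + 1` counts the
#'   occurrences of digit `i`.
#' @examples
#' dye_count("1.02..0.0.2", 3)  # 3 1 2
#' @export
dye_count <- function(d, n_colors) {
  stopifnot(is.character(d), length(d) == 1L)
  chars <- strsplit(d, "", fixed = TRUE)[[1]]
  vapply(seq_len(n_colors) - 1L,
         function(i) sum(chars == as.character(i)), integer(1))
}

#' Prefix test on dye sequences
#'
#' Indicator that dye sequence `d` begins with `r` character for character.
#' The empty prefix matches everything.
#'
#' @param r Prefix string (colors and dots).
#' @param d Dye-sequence string.
#' @return 1L or 0L.
#' @export
dseq_starts_with <- function(r, d) {
  as.integer(startsWith(d, r))
}

#' Build the peptide classification database
#'
#' Assembles peptides, their dye sequences, the uniform peptide prior `P_P`
#' and the induced dye-sequence prior `P_D` (the summed prior of the peptides
#' sharing each dye sequence).  Proteins are digested with [digest_trypsin()]
#' first.  Duplicate peptide sequences are collapsed to one entry, and
#' peptides whose dye sequence is empty are excluded from the database (they
#' emit no informative signal); exclusions are reported via [message()].
#'
#' @param sequences Character vector of peptides (default) or proteins.
#' @param scheme A [label_scheme()].
#' @param type `"peptides"` or `"proteins"`.
#' @return A `pb_database` with components `peptides` (data.frame: `id`,
#'   `sequence`, `dye_seq`, `dseq_id`), `dye_seqs` (data.frame: `id`,
#'   `dye_seq`, `prior`, `n_peptides`), `prior_p`, `scheme`, `n_colors`, and
#'   `dropped` (excluded peptide sequences).
#' @examples
#' sch <- label_scheme(list(c("D", "E"), "C"))
#' db <- build_database(c("ACDK", "AEEK", "GGK", "ACDK"), sch)
#' db$dye_seqs
#' @export
build_database <- function(sequences, scheme, type = c("peptides", "proteins")) {
  type <- match.arg(type)
  stopifnot(inherits(scheme, "pb_scheme"), length(sequences) >= 1L)
  peptides <- if (type == "proteins") {
    unlist(lapply(sequences, digest_trypsin), use.names = FALSE)
  } else {
    toupper(as.character(sequences))
  }
  if (any(!nzchar(peptides))) stop("empty peptide sequence")
  if (any(grepl("[^A-Z]", peptides))) stop("peptides must use letters A-Z only")
  peptides <- unique(peptides)
  nd <- attr(scheme, "n_colors")
  dseq <- vapply(peptides, to_dye_sequence, character(1),
                 scheme = scheme, USE.NAMES = FALSE)
  dark <- !nzchar(dseq)
  dropped <- peptides[dark]
  if (length(dropped)) {
    message(sprintf("dropping %d peptide(s) with no labelable residue: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  peptides <- peptides[!dark]
  dseq <- dseq[!dark]
  if (length(peptides) == 0L) stop("no peptide carries a labelable residue")

  uniq <- unique(dseq)
  dseq_id <- match(dseq, uniq)
  n_p <- length(peptides)
  prior_p <- rep.int(1 / n_p, n_p)
  prior_d <- vapply(seq_along(uniq),
                    function(j) sum(prior_p[dseq_id == j]), numeric(1))
  pep_tab <- data.frame(id = seq_len(n_p), sequence = peptides,
                        dye_seq = dseq, dseq_id = dseq_id,
                        stringsAsFactors = FALSE)
  dseq_tab <- data.frame(id = seq_along(uniq), dye_seq = uniq,
                         prior = prior_d,
                         n_peptides = tabulate(dseq_id, length(uniq)),
                         stringsAsFactors = FALSE)
  db <- structure(list(peptides = pep_tab, dye_seqs = dseq_tab,
                       prior_p = prior_p, scheme = scheme, n_colors = nd,
                       dropped = dropped, .env = new.env(parent = emptyenv())),
                  class = "pb_database")
  db
}

#' @export
print.pb_database <- function(x, ...) {
  cat(sprintf("peptide database: %d peptides, %d dye sequences, %d color(s)\n",
              nrow(x$peptides), nrow(x$dye_seqs), x$n_colors))
  if (length(x$dropped))
    cat(sprintf("  (%d unlabeled peptide(s) excluded)\n", length(x$dropped)))
  invisible(x)
}

# compiled prefix index handle; built lazily, cached per session
db_ptr <- function(db) {
  stopifnot(inherits(db, "pb_database"))
  env <- db$.env
  if (is.null(env$ptr) || !pb_ptr_ok(env$ptr)) {
    ids <- split(db$peptides$id, db$peptides$dseq_id)
    ws <- split(db$prior_p[db$peptides$id], db$peptides$dseq_id)
    ord <- as.character(db$dye_seqs$id)
    env$ptr <- pb_db_build(db$dye_seqs$dye_seq, db$dye_seqs$prior,
                           ids[ord], ws[ord], db$n_colors)
  }
  env$ptr
}
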