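# Exact MAP decoder by exhaustive trajectory enumeration.  Independent of the
# beam decoder: it never uses the (N, K, R) state machinery or the compiled
# transition code.  Per dye sequence it enumerates every hidden outcome --
# which fluorophores attached, and per cycle detachment, each dye-loss
# subset, and Edman success/failure -- tracking per-residue dye presence
# exactly, and collapses the outcomes to distinct attached-count histories
# with summed probabilities.  The read likelihood is then a weighted sum of
# Gaussian density products over those histories.

#' Enumerate the attached-count histories of a dye sequence
#'
#' @param d Dye-sequence string.
#' @param params A [probeam_params()].
#' @param cap Maximum number of partial trajectories carried; exceeding it is
#'   an error asking for a smaller instance.
#' @return List with `K` (integer matrix, one row per distinct history, one
#'   column per (cycle, color) cell, color fastest) and `logp` (log
#'   probabilities; `sum(exp(logp)) == 1`).
#' @keywords internal
dseq_trajectories <- function(d, params, cap = 2e5) {
  nd <- params$n_colors
  nc <- params$n_cycles
  chars <- if (nzchar(d)) strsplit(d, "", fixed = TRUE)[[1]] else character(0)
  labpos <- which(chars != ".")
  L <- length(labpos)
  if (L > 16L)
    stop("too many labeled residues for exhaustive enumeration; shrink the instance")
  cols <- as.integer(chars[labpos])
  nmask <- bitwShiftL(1L, L)
  Ktab <- matrix(0L, nmask, nd)
  if (L > 0) for (b in seq_len(L)) {
    has <- bitwAnd(0:(nmask - 1L), bitwShiftL(1L, b - 1L)) > 0L
    Ktab[has, cols[b] + 1L] <- Ktab[has, cols[b] + 1L] + 1L
  }
  popc <- as.integer(rowSums(Ktab))
  bit_of_pos <- integer(length(chars))
  bit_of_pos[labpos] <- bitwShiftL(1L, seq_len(L) - 1L)

  hkey <- function(h) paste(h, collapse = ",")
  cur <- new.env(parent = emptyenv())
  put <- function(env, j, mask, hist, p) {
    key <- if (mask == 0L) paste0("D:", hkey(hist))
           else paste0(j, ":", mask, ":", hkey(hist))
    e <- get0(key, envir = env)
    if (is.null(e)) assign(key, list(j = j, mask = mask, hist = hist, p = p),
                           envir = env)
    else {
      e$p <- e$p + p
      assign(key, e, envir = env)
    }
  }

  # dye miss before the first observation
  for (mask in 0:(nmask - 1L)) {
    p0 <- params$m^(L - popc[mask + 1L]) * (1 - params$m)^popc[mask + 1L]
    if (p0 > 0) put(cur, 0L, mask, Ktab[mask + 1L, ], p0)
  }

  zeros <- rep.int(0L, nd)
  for (t in seq_len(nc)) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(cur, all.names = TRUE)) {
      en <- get(key, envir = cur)
      if (en$mask == 0L) { # dark or detached: absorbing
        put(nxt, en$j, 0L, c(en$hist, zeros), en$p)
        next
      }
      # detachment
      if (params$p_d > 0)
        put(nxt, en$j, 0L, c(en$hist, zeros), en$p * params$p_d)
      surv <- en$p * (1 - params$p_d)
      if (surv <= 0) next
      pcm <- popc[en$mask + 1L]
      sub <- en$mask
      repeat {
        pcs <- popc[sub + 1L]
        pl <- params$l^(pcm - pcs) * (1 - params$l)^pcs
        if (pl > 0) {
          # Edman failure: residue chain unchanged
          if (params$e > 0)
            put(nxt, en$j, sub, c(en$hist, Ktab[sub + 1L, ]), surv * pl * params$e)
          # Edman success: consume the front residue
          jj <- en$j + 1L
          newmask <- if (bit_of_pos[jj] > 0L)
            bitwAnd(sub, bitwNot(bit_of_pos[jj])) else sub
          put(nxt, jj, newmask, c(en$hist, Ktab[newmask + 1L, ]),
              surv * pl * (1 - params$e))
        }
        if (sub == 0L) break
        sub <- bitwAnd(sub - 1L, en$mask)
      }
    }
    cur <- nxt
    if (length(ls(cur, all.names = TRUE)) > cap)
      stop("trajectory enumeration exceeded the cap; shrink the instance")
  }

  out <- new.env(parent = emptyenv())
  for (key in ls(cur, all.names = TRUE)) {
    en <- get(key, envir = cur)
    k2 <- hkey(en$hist)
    assign(k2, (get0(k2, envir = out) %||% 0) + en$p, envir = out)
  }
  keys <- ls(out, all.names = TRUE)
  K <- t(vapply(strsplit(keys, ",", fixed = TRUE),
                function(v) as.integer(v), integer((nc + 1L) * nd)))
  if (nd * (nc + 1L) == 1L) K <- matrix(as.integer(K), ncol = 1L)
  list(K = K, logp = log(vapply(keys, get, numeric(1), envir = out,
                                USE.NAMES = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# per-read log likelihood of a trajectory table
traj_loglik_one <- function(traj, x, params) {
  xv <- as.vector(x) # color fastest, cycle-major: matches trajectory columns
  Kmax <- max(traj$K, 0L)
  ks <- 0:Kmax
  ld <- vapply(ks, function(k)
    dnorm(xv, k * params$mu, sigma_eff(k, params), log = TRUE),
    numeric(length(xv)))           # cells x (Kmax+1)
  ldv <- as.vector(t(ld))          # (cell-1)*(Kmax+1) + k + 1
  idx <- (col(traj$K) - 1L) * (Kmax + 1L) + traj$K + 1L
  ll <- traj$logp + rowSums(matrix(ldv[idx], nrow = nrow(traj$K)))
  logsumexp(ll)
}

#' Exact read likelihood of a dye sequence
#'
#' `P(X | D = d)` by exhaustive enumeration of every dye-miss, detachment,
#' dye-loss and Edman outcome, summing outcome probabilities times Gaussian
#' emission densities.
#'
#' @param d Dye-sequence string.
#' @param read Intensity matrix, `n_colors` by `n_cycles + 1`.
#' @param params A [probeam_params()].
#' @param log Return the log likelihood instead.
#' @param cap Trajectory cap, see [dseq_trajectories()].
#' @return Likelihood (a density value), or its log.
#' @export
likelihood_exact <- function(d, read, params, log = FALSE, cap = 2e5) {
  read <- as.matrix(read)
  stopifnot(nrow(read) == params$n_colors, ncol(read) == params$n_cycles + 1L)
  ll <- traj_loglik_one(dseq_trajectories(d, params, cap), read, params)
  if (log) ll else exp(ll)
}

#' Exact MAP peptide decoding
#'
#' The maximum-a-posteriori classifier `argmax_p P(X | T(p)) P_P(p)` with the
#' likelihood computed exactly; the accuracy ceiling for any decoder under
#' this model, and the verification oracle for the beam decoder.
#'
#' @param db A [build_database()] result.
#' @param read Intensity matrix, `n_colors` by `n_cycles + 1`.
#' @param params A [probeam_params()].
#' @param cap Trajectory cap per dye sequence.
#' @return A `pb_decode`, as [decode_read()].
#' @export
decode_map_exact <- function(db, read, params, cap = 2e5) {
  read <- as.matrix(read)
  arr <- array(0, c(1L, nrow(read), ncol(read)))
  arr[1, , ] <- read
  res <- decode_map_exact_batch(db, arr, params, cap = cap)
  decode_result(db, attr(res, "posterior")[1, ], FALSE, FALSE, top_k = 2L)
}

#' @rdname decode_map_exact
#' @param reads A `pb_reads` object or 3-d array `[read, color, cycle]`.
#' @return For the batch variant, a data.frame shaped like [decode_batch()]
#'   output with the posterior matrix as attribute `"posterior"`.
#' @export
decode_map_exact_batch <- function(db, reads, params, cap = 2e5) {
  arr <- if (inherits(reads, "pb_reads")) reads$intensities else reads
  stopifnot(length(dim(arr)) == 3L, dim(arr)[2] == params$n_colors,
            dim(arr)[3] == params$n_cycles + 1L)
  n <- dim(arr)[1]
  cells <- dim(arr)[2] * dim(arr)[3]
  xmat <- matrix(aperm(arr, c(2, 3, 1)), nrow = cells) # cells x reads

  trajs <- lapply(db$dye_seqs$dye_seq, dseq_trajectories,
                  params = params, cap = cap)
  Kmax <- max(vapply(trajs, function(tr) max(tr$K, 0L), integer(1)))
  # emission log densities for every (cell, k) against every read
  ldm <- matrix(0, cells * (Kmax + 1L), n)
  for (k in 0:Kmax) {
    rows <- seq_len(cells) * (Kmax + 1L) - (Kmax - k)
    ldm[rows, ] <- dnorm(xmat, k * params$mu, sigma_eff(k, params), log = TRUE)
  }
  loglik <- matrix(NA_real_, n, length(trajs))
  for (j in seq_along(trajs)) {
    tr <- trajs[[j]]
    npaths <- nrow(tr$K)
    O <- matrix(0, npaths, cells * (Kmax + 1L))
    idx <- (col(tr$K) - 1L) * (Kmax + 1L) + tr$K + 1L
    O[cbind(rep(seq_len(npaths), cells), as.vector(idx))] <- 1
    pl <- O %*% ldm + tr$logp             # npaths x reads
    mx <- apply(pl, 2, max)
    loglik[, j] <- mx + log(colSums(exp(sweep(pl, 2, mx, "-"))))
  }
  # peptide posterior: prior times the likelihood of the peptide's dye sequence
  lp <- sweep(loglik[, db$peptides$dseq_id, drop = FALSE], 2,
              log(db$prior_p), "+")
  mx <- apply(lp, 1, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)

  pred <- max.col(post, ties.method = "first")
  second <- if (ncol(post) >= 2L) {
    tmp <- post
    tmp[cbind(seq_len(n), pred)] <- -Inf
    max.col(tmp, ties.method = "first")
  } else rep(NA_integer_, n)
  out <- data.frame(
    read_id = if (inherits(reads, "pb_reads")) reads$read_id else seq_len(n),
    predicted_peptide_id = pred,
    peptide_sequence = db$peptides$sequence[pred],
    posterior = post[cbind(seq_len(n), pred)],
    runner_up_id = second,
    runner_up_posterior = if (ncol(post) >= 2L)
      post[cbind(seq_len(n), second)] else rep(NA_real_, n),
    pruned = FALSE,
    undecodable = FALSE,
    stringsAsFactors = FALSE
  )
  attr(out, "posterior") <- post
  out
}
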