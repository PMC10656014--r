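# Shared fixtures and independent reference implementations used as oracles.
# Everything here is deliberately simple, unvectorized R so it shares no code
# path with the compiled decoder.

scheme2 <- function() label_scheme(list(c("D", "E"), c("C", "Y")))
scheme3 <- function() label_scheme(list(c("D", "E"), "C", "Y"))
scheme_tbl2 <- function() label_scheme(list(c("C", "E"), "K", "D"))

lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# brute-force eta: full scan, no index
bf_eta <- function(db, N, R) {
  hits <- vapply(db$dye_seqs$dye_seq, function(d) {
    startsWith(d, R) &&
      identical(dye_count(substr(d, nchar(R) + 1L, nchar(d)), db$n_colors),
                as.integer(N))
  }, logical(1), USE.NAMES = FALSE)
  db$dye_seqs$dye_seq[hits]
}

# brute-force one-cycle transition: compose the three phases by direct
# enumeration with stats::dbinom and the scanned eta, then (optionally)
# filter composed successors against the observation
bf_transitions <- function(db, s, params, x = NULL) {
  acc <- new.env(parent = emptyenv())
  add <- function(st, p) {
    k <- state_key(st)
    cur <- get0(k, envir = acc)
    if (is.null(cur)) assign(k, list(state = st, p = p), envir = acc)
    else {
      cur$p <- cur$p + p
      assign(k, cur, envir = acc)
    }
  }
  nd <- db$n_colors
  if (all(s$K == 0L)) {
    add(s, 1)
  } else {
    add(pb_state(s$N, rep.int(0L, nd), s$R), params$p_d)
    kgrid <- expand.grid(lapply(s$K, function(k) 0:k))
    for (r in seq_len(nrow(kgrid))) {
      kp <- as.integer(unlist(kgrid[r, ]))
      base <- (1 - params$p_d) * prod(dbinom(kp, s$K, 1 - params$l))
      s1 <- pb_state(s$N, kp, s$R)
      if (all(kp == 0L)) {
        add(s1, base)
        next
      }
      add(s1, base * params$e) # Edman failure
      mem <- bf_eta(db, s$N, s$R)
      w <- db$dye_seqs$prior[match(mem, db$dye_seqs$dye_seq)]
      nxt <- ifelse(nchar(mem) > nchar(s$R),
                    substr(mem, nchar(s$R) + 1L, nchar(s$R) + 1L), ".")
      for (a in unique(nxt)) {
        prem <- sum(w[nxt == a]) / sum(w)
        pa_succ <- (1 - params$e) * prem
        if (a == ".") {
          add(append_removed(s1, "."), base * pa_succ)
        } else {
          i <- as.integer(a)
          pda <- kp[i + 1L] / s$N[i + 1L]
          N2 <- s$N
          N2[i + 1L] <- N2[i + 1L] - 1L
          if (pda > 0) {
            K2 <- kp
            K2[i + 1L] <- K2[i + 1L] - 1L
            add(pb_state(N2, K2, paste0(s$R, a)), base * pa_succ * pda)
          }
          if (pda < 1) {
            add(pb_state(N2, kp, paste0(s$R, a)), base * pa_succ * (1 - pda))
          }
        }
      }
    }
  }
  keys <- ls(acc, all.names = TRUE)
  out <- data.frame(key = keys,
                    p = vapply(keys, function(k) get(k, envir = acc)$p,
                               numeric(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(x)) {
    pass <- vapply(keys, function(k)
      prune_pass(x, get(k, envir = acc)$state$K, params), logical(1))
    out <- out[pass, ]
  }
  out[out$p > 0, ]
}

transitions_as_df <- function(tr) {
  data.frame(key = vapply(tr$states, state_key, character(1)),
             p = tr$prob, stringsAsFactors = FALSE)
}

# a state guaranteed consistent with the database: a random split of a
# random database dye sequence, with K sampled below the suffix counts
random_state <- function(db) {
  d <- sample(db$dye_seqs$dye_seq, 1)
  cut <- sample(0:nchar(d), 1)
  N <- dye_count(substr(d, cut + 1L, nchar(d)), db$n_colors)
  K <- vapply(N, function(n) sample(0:n, 1), integer(1))
  pb_state(N, K, substr(d, 1, cut))
}

small_db <- function(n = 8, seed = NULL, scheme = scheme2(),
                     length_range = c(4, 9)) {
  make_random_database(n, length_range, scheme, seed = seed)
}

# exhaustive top-N_B initial states by p_alpha, with the same canonical
# tie-break (byte order on the state key) as the greedy search
exhaustive_initial_keys <- function(db, x0, params) {
  nd <- db$n_colors
  ckey <- vapply(db$dye_seqs$dye_seq,
                 function(d) paste(dye_count(d, nd), collapse = ","),
                 character(1), USE.NAMES = FALSE)
  pn <- numeric(0)
  for (j in seq_along(ckey)) {
    k <- ckey[j]
    pn[k] <- if (is.na(pn[k])) db$dye_seqs$prior[j] else
      pn[k] + db$dye_seqs$prior[j]
  }
  keys <- character(0)
  lp <- numeric(0)
  for (k in names(pn)) {
    N <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    kgrid <- expand.grid(lapply(N, function(n) 0:n))
    for (r in seq_len(nrow(kgrid))) {
      K <- as.integer(unlist(kgrid[r, ]))
      s <- pb_state(N, K, "")
      keys <- c(keys, state_key(s))
      lp <- c(lp, (log(pn[[k]]) + obs_logprob(x0, K, params)) +
                log(prod(dbinom(K, N, 1 - params$m))))
    }
  }
  ord <- order(-lp, keys, method = "radix")
  keys[ord[seq_len(min(params$n_beam, length(keys)))]]
}
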