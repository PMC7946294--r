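# Independent brute-force implementation of the integrated-information
# computations, used as a test oracle. Everything here is written against the
# definitions directly, with plain data frames of state bit patterns and an
# exact min-cost-flow earth mover's distance of its own; no code is shared
# with the package engine.

# state table: row i = bits of state i-1, first node = least significant
or_states_cache <- new.env()
or_states <- function(n) {
  key <- as.character(n)
  v <- get0(key, envir = or_states_cache)
  if (is.null(v)) {
    v <- as.matrix(expand.grid(rep(list(0:1), n)))
    dimnames(v) <- NULL
    assign(key, v, envir = or_states_cache)
  }
  v
}

# exact EMD by successive shortest paths over the residual transport graph
or_emd <- function(p, q, cost) {
  tol <- 1e-12
  a <- length(p)
  rp <- p
  rq <- q
  m <- pmin(rp, rq)
  rp <- rp - m
  rq <- rq - m
  fl <- matrix(0, a, a)
  while (sum(rp) > tol) {
    du <- ifelse(rp > tol, 0, Inf)
    dv <- rep(Inf, a)
    pre_v <- integer(a)
    pre_u <- integer(a)
    repeat {
      changed <- FALSE
      cand <- du + cost
      arg <- max.col(-t(cand), ties.method = "first")
      mn <- cand[cbind(arg, seq_len(a))]
      upd <- mn < dv - 1e-15
      if (any(upd)) {
        dv[upd] <- mn[upd]
        pre_v[upd] <- arg[upd]
        changed <- TRUE
      }
      candr <- matrix(dv, a, a, byrow = FALSE) - t(cost)  # from demand j to supply i
      candr[t(fl) <= tol] <- Inf
      argr <- max.col(-t(candr), ties.method = "first")
      mnr <- candr[cbind(argr, seq_len(a))]
      updr <- mnr < du - 1e-15
      if (any(updr)) {
        du[updr] <- mnr[updr]
        pre_u[updr] <- argr[updr]
        changed <- TRUE
      }
      if (!changed) break
    }
    js <- which(rq > tol)
    j <- js[which.min(dv[js])]
    path_i <- integer(0)
    path_j <- integer(0)
    cj <- j
    repeat {
      ci <- pre_v[cj]
      path_i <- c(ci, path_i)
      path_j <- c(cj, path_j)
      if (pre_u[ci] == 0) break
      cj <- pre_u[ci]
      if (length(path_i) > 2 * a) stop("oracle emd: path trace failed")
    }
    bott <- min(rp[path_i[1]], rq[j])
    if (length(path_i) > 1) {
      for (k in 2:length(path_i)) bott <- min(bott, fl[path_i[k], path_j[k - 1]])
    }
    for (k in seq_along(path_i)) {
      fl[path_i[k], path_j[k]] <- fl[path_i[k], path_j[k]] + bott
    }
    if (length(path_i) > 1) {
      for (k in 2:length(path_i)) {
        fl[path_i[k], path_j[k - 1]] <- fl[path_i[k], path_j[k - 1]] - bott
      }
    }
    rp[path_i[1]] <- rp[path_i[1]] - bott
    rq[j] <- rq[j] - bott
  }
  sum(fl * cost)
}

or_cost_cache <- new.env()
or_hamming_cost <- function(nbits) {
  key <- as.character(nbits)
  v <- get0(key, envir = or_cost_cache)
  if (is.null(v)) {
    st <- or_states(nbits)
    nst <- nrow(st)
    v <- matrix(0, nst, nst)
    for (i in seq_len(nst)) {
      for (j in seq_len(nst)) v[i, j] <- sum(st[i, ] != st[j, ])
    }
    assign(key, v, envir = or_cost_cache)
  }
  v
}

or_emd_hamming <- function(p, q) {
  nbits <- round(log2(length(p)))
  or_emd(p, q, or_hamming_cost(nbits))
}

# transportation LP via pracma::linprog, for validating or_emd itself
or_emd_lp <- function(p, q, cost) {
  n <- length(p)
  aeq <- matrix(0, 2 * n - 1, n * n)
  for (i in seq_len(n)) aeq[i, (seq_len(n) - 1) * n + i] <- 1
  for (j in seq_len(n - 1)) aeq[n + j, (j - 1) * n + seq_len(n)] <- 1
  res <- pracma::linprog(as.vector(cost), Aeq = aeq, beq = c(p, q[-n]),
                         maxiter = 2000)
  res$fval
}

# mean of column j over the rows where the given nodes carry the given bits
or_col_mean <- function(tpm, nodes, bits, j) {
  n <- round(log2(nrow(tpm)))
  st <- or_states(n)
  keep <- rep(TRUE, nrow(st))
  for (k in seq_along(nodes)) keep <- keep & st[, nodes[k]] == bits[k]
  mean(tpm[keep, j])
}

or_effect_rep <- function(tpm, mech, ms, purview) {
  marg <- vapply(purview, function(j) or_col_mean(tpm, mech, ms, j), numeric(1))
  pst <- or_states(length(purview))
  apply(pst, 1, function(z) prod(ifelse(z == 1, marg, 1 - marg)))
}

or_cause_rep <- function(tpm, mech, ms, purview) {
  pst <- or_states(length(purview))
  lik <- apply(pst, 1, function(z) {
    l <- 1
    for (k in seq_along(mech)) {
      on <- or_col_mean(tpm, purview, z, mech[k])
      l <- l * if (ms[k] == 1) on else 1 - on
    }
    l
  })
  if (length(mech) == 0) lik <- rep(1, nrow(pst))
  tot <- sum(lik)
  if (tot <= 0) rep(1 / nrow(pst), nrow(pst)) else lik / tot
}

# all unordered bipartitions {(M1,P1),(M2,P2)} of (mech, purview) with the
# doubly-empty part excluded
or_partitions <- function(mech, purview) {
  subsets <- function(v) {
    out <- list(integer(0))
    for (x in v) out <- c(out, lapply(out, function(s) c(s, x)))
    out
  }
  key <- function(m, p) paste(paste(m, collapse = "."), paste(p, collapse = "."), sep = "|")
  parts <- list()
  seen <- character(0)
  for (m1 in subsets(mech)) {
    for (p1 in subsets(purview)) {
      m2 <- setdiff(mech, m1)
      p2 <- setdiff(purview, p1)
      if (length(m1) + length(p1) == 0) next
      if (length(m2) + length(p2) == 0) next
      k <- paste(sort(c(key(m1, p1), key(m2, p2))), collapse = "~")
      if (k %in% seen) next
      seen <- c(seen, k)
      parts[[length(parts) + 1]] <- list(m1 = m1, p1 = p1, m2 = m2, p2 = p2)
    }
  }
  parts
}

or_part_rep <- function(tpm, part, ms_of, cause_dir) {
  one_side <- function(m, p) {
    if (length(p) == 0) return(NULL)
    if (cause_dir) {
      or_cause_rep(tpm, m, ms_of(m), p)
    } else {
      or_effect_rep(tpm, m, ms_of(m), p)
    }
  }
  list(r1 = one_side(part$m1, part$p1), r2 = one_side(part$m2, part$p2))
}

# combine two part repertoires into the purview-local joint
or_combine <- function(r1, p1, r2, p2, purview) {
  pst <- or_states(length(purview))
  apply(pst, 1, function(z) {
    v <- 1
    if (length(p1)) {
      idx <- sum(z[match(p1, purview)] * 2^(seq_along(p1) - 1)) + 1
      v <- v * r1[idx]
    }
    if (length(p2)) {
      idx <- sum(z[match(p2, purview)] * 2^(seq_along(p2) - 1)) + 1
      v <- v * r2[idx]
    }
    v
  })
}

# marginal on-probability of each purview node under a purview-local joint
or_joint_marginals <- function(rep, purview) {
  pst <- or_states(length(purview))
  vapply(seq_along(purview), function(k) sum(rep[pst[, k] == 1]), numeric(1))
}

or_phi_mip <- function(tpm, mech, ms, purview, cause_dir) {
  ms_of <- function(m) ms[match(m, mech)]
  best <- Inf
  if (cause_dir) {
    whole <- or_cause_rep(tpm, mech, ms, purview)
    cost <- or_hamming_cost(length(purview))
  } else {
    whole <- or_effect_rep(tpm, mech, ms, purview)
    wm <- or_joint_marginals(whole, purview)
  }
  for (part in or_partitions(mech, purview)) {
    pr <- or_part_rep(tpm, part, ms_of, cause_dir)
    partd <- or_combine(pr$r1, part$p1, pr$r2, part$p2, purview)
    d <- if (cause_dir) {
      or_emd(whole, partd, cost)
    } else {
      # both sides factorize over purview nodes, so the EMD under the Hamming
      # metric is the sum of marginal differences (checked against or_emd in
      # the EMD test file)
      sum(abs(wm - or_joint_marginals(partd, purview)))
    }
    if (d < best) best <- d
  }
  max(best, 0)
}

or_all_purviews <- function(n) {
  out <- list()
  for (sz in seq_len(n)) {
    cmb <- combn(n, sz)
    for (i in seq_len(ncol(cmb))) out[[length(out) + 1]] <- cmb[, i]
  }
  out
}

or_core <- function(tpm, mech, ms, cause_dir) {
  n <- round(log2(nrow(tpm)))
  purviews <- or_all_purviews(n)
  phis <- vapply(purviews, function(p) or_phi_mip(tpm, mech, ms, p, cause_dir),
                 numeric(1))
  cand <- which(phis >= max(phis) - 1e-12)
  sizes <- lengths(purviews[cand])
  cand <- cand[sizes == max(sizes)]
  if (length(cand) > 1) {
    keys <- vapply(purviews[cand], function(p) paste(sprintf("%02d", p), collapse = ""),
                   character(1))
    cand <- cand[order(keys)]
  }
  list(purview = purviews[[cand[1]]], phi = phis[cand[1]])
}

# expanded repertoires over the full n-node space (off-purview max-entropy)
or_expand_cause <- function(tpm, mech, ms, purview) {
  n <- round(log2(nrow(tpm)))
  r <- or_cause_rep(tpm, mech, ms, purview)
  st <- or_states(n)
  apply(st, 1, function(z) {
    idx <- sum(z[purview] * 2^(seq_along(purview) - 1)) + 1
    r[idx] / 2^(n - length(purview))
  })
}

or_expand_effect_marginals <- function(tpm, mech, ms, purview) {
  n <- round(log2(nrow(tpm)))
  m <- rep(0.5, n)
  for (j in purview) m[j] <- or_col_mean(tpm, mech, ms, j)
  m
}

# concepts for every mechanism at its state under `state`; returns a list
# keyed by mechanism with phis, core purviews, and expanded repertoires
or_ces <- function(tpm, state, cache = NULL) {
  n <- round(log2(nrow(tpm)))
  mechs <- or_all_purviews(n)
  out <- list()
  for (mi in seq_along(mechs)) {
    mech <- mechs[[mi]]
    ms <- state[mech]
    key <- paste(paste(mech, collapse = "."), paste(ms, collapse = ""), sep = "@")
    if (!is.null(cache)) {
      hit <- get0(key, envir = cache)
      if (!is.null(hit)) {
        out[[mi]] <- hit
        next
      }
    }
    cc <- or_core(tpm, mech, ms, cause_dir = TRUE)
    ce <- or_core(tpm, mech, ms, cause_dir = FALSE)
    entry <- list(
      mechanism = mech,
      phi_cause = cc$phi, phi_effect = ce$phi,
      phi = min(cc$phi, ce$phi),
      core_cause = cc$purview, core_effect = ce$purview,
      cause_full = or_expand_cause(tpm, mech, ms, cc$purview),
      effect_marg = or_expand_effect_marginals(tpm, mech, ms, ce$purview)
    )
    out[[mi]] <- entry
    if (!is.null(cache)) assign(key, entry, envir = cache)
  }
  out
}

or_apply_cut <- function(tpm, from) {
  n <- round(log2(nrow(tpm)))
  st <- or_states(n)
  to <- setdiff(seq_len(n), from)
  out <- tpm
  for (si in seq_len(nrow(st))) {
    for (j in to) {
      keep_nodes <- setdiff(seq_len(n), from)
      out[si, j] <- or_col_mean(tpm, keep_nodes, st[si, keep_nodes], j)
    }
  }
  out
}

or_ces_distance <- function(tpm_f, ces_f, tpm_c, ces_c, n) {
  cost <- or_hamming_cost(n)
  unif <- rep(1 / 2^n, 2^n)
  unc_f <- vapply(seq_len(n), function(j) mean(tpm_f[, j]), numeric(1))
  unc_c <- vapply(seq_len(n), function(j) mean(tpm_c[, j]), numeric(1))
  total <- 0
  for (mi in seq_along(ces_f)) {
    ef <- ces_f[[mi]]
    ec <- ces_c[[mi]]
    w <- min(ef$phi, ec$phi)
    if (w > 0) {
      total <- total + w * (or_emd(ef$cause_full, ec$cause_full, cost) +
                              sum(abs(ef$effect_marg - ec$effect_marg)))
    }
    resid <- abs(ef$phi - ec$phi)
    if (resid > 0) {
      if (ef$phi >= ec$phi) {
        big <- ef
        unc <- unc_f
      } else {
        big <- ec
        unc <- unc_c
      }
      total <- total + resid * (or_emd(big$cause_full, unif, cost) +
                                  sum(abs(big$effect_marg - unc)))
    }
  }
  total
}

# per-state system-level integrated information; memoizes concepts across
# states within each (full or cut) system
or_big_phi_all <- function(tpm) {
  n <- round(log2(nrow(tpm)))
  st <- or_states(n)
  cuts <- list()
  for (from_sz in seq_len(n - 1)) {
    cmb <- combn(n, from_sz)
    for (i in seq_len(ncol(cmb))) cuts[[length(cuts) + 1]] <- cmb[, i]
  }
  cache_f <- new.env()
  ces_f <- lapply(seq_len(nrow(st)), function(si) or_ces(tpm, st[si, ], cache_f))
  best <- rep(Inf, nrow(st))
  for (cut in cuts) {
    tpm_c <- or_apply_cut(tpm, cut)
    cache_c <- new.env()
    for (si in seq_len(nrow(st))) {
      d <- or_ces_distance(tpm, ces_f[[si]], tpm_c,
                           or_ces(tpm_c, st[si, ], cache_c), n)
      if (d < best[si]) best[si] <- d
    }
  }
  best
}

# random state-by-node TPM
random_tpm <- function(n, seed) {
  withr::with_seed(seed, matrix(runif(2^n * n), 2^n, n))
}
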