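# independent oracle implementations shared across test files; these
# re-derive expected results by brute force and must stay decoupled from
# the package internals they check

# greedy distance clumping by explicit iteration
oracle_distance_clump <- function(pos, p, window, gws) {
  assigned <- rep(FALSE, length(pos))
  loci <- list()
  repeat {
    cand <- which(!assigned & p <= gws)
    if (!length(cand)) break
    top <- cand[order(p[cand])][1]
    members <- which(!assigned & abs(pos - pos[top]) <= window)
    loci[[length(loci) + 1L]] <- sort(members)
    assigned[members] <- TRUE
  }
  loci
}

# step-by-step locus-breaker trace: distance clumping for leads, chain
# clustering of sub-threshold variants, GWS retention, oversize splitting
oracle_locus_breaker <- function(pos, p, p_cluster = 1e-5, gap = 2.5e5,
                                 gws = 1e-8, max_span = 1.5e6,
                                 half_window = 7.5e5, window = 5e5) {
  leads <- integer(0)
  assigned <- rep(FALSE, length(pos))
  repeat {
    cand <- which(!assigned & p <= gws)
    if (!length(cand)) break
    top <- cand[order(p[cand])][1]
    leads <- c(leads, top)
    assigned[abs(pos - pos[top]) <= window & !assigned] <- TRUE
  }
  keep <- which(p < p_cluster)
  if (!length(keep)) return(list())
  keep <- keep[order(pos[keep])]
  out <- list()
  cl_start <- 1L
  kpos <- pos[keep]
  breaks <- c(which(diff(kpos) > gap), length(keep))
  for (b in breaks) {
    idx <- keep[cl_start:b]
    cl_start <- b + 1L
    if (!any(p[idx] <= gws)) next
    span <- max(pos[idx]) - min(pos[idx])
    if (span <= max_span) {
      out[[length(out) + 1L]] <- sort(idx)
    } else {
      in_cl <- leads[leads %in% idx]
      lp <- pos[in_cl]
      for (j in seq_along(in_cl)) {
        near <- vapply(idx, function(i) {
          which.min(abs(pos[i] - lp)) == j &&
            abs(pos[i] - lp[j]) <= half_window
        }, logical(1))
        if (any(near)) out[[length(out) + 1L]] <- sort(idx[near])
      }
    }
  }
  out
}

# independent transcription of the PICS proxy weighting
oracle_pics_pips <- function(r2, S, exponent = 6.4) {
  w <- vapply(r2, function(x) {
    mu <- x * S
    sd <- sqrt(max(0, 1 - x^(exponent / 2))) * sqrt(S) / 2
    if (sd == 0) {
      if (abs(S - mu) < 1e-12) 1 else 0
    } else {
      2 * stats::pnorm((S - mu) / sd, lower.tail = FALSE)
    }
  }, numeric(1))
  w / sum(w)
}
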