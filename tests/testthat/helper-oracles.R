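# Independent reference implementations used as oracles. These deliberately
# re-derive each quantity by a different route than the package.

# HWE exact test via the Wigginton-style recurrence on heterozygote counts
# (the package enumerates log-factorial probabilities directly).
oracle_hwe <- function(aa, ab, bb) {
  n <- aa + ab + bb
  na <- 2 * bb + ab
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  if (length(hets) > 1) {
    for (k in seq_len(length(hets) - 1)) {
      h <- hets[k]
      hom_b <- (na - h) / 2
      hom_a <- n - hom_b - h
      # P(h+2) / P(h) = 4 * hom_a * hom_b / ((h+2) * (h+1))
      pr[k + 1] <- pr[k] * 4 * hom_a * hom_b / ((h + 2) * (h + 1))
    }
  }
  pr <- pr / sum(pr)
  obs <- pr[hets == ab]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# exhaustive windowed pruning reference: after every removal, re-scan every
# window from scratch over the surviving set
oracle_prune <- function(dos, chrom, r2_max, window, step, pvals) {
  m <- ncol(dos)
  for (j in seq_len(m)) {
    x <- dos[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    dos[, j] <- x
  }
  alive <- rep(TRUE, m)
  repeat {
    removed <- FALSE
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      starts <- if (length(idx) <= window) 0L
                else seq.int(0L, length(idx) - 1L, by = step)
      for (s in starts) {
        win <- idx[(s + 1L):min(s + window, length(idx))]
        act <- win[alive[win]]
        if (length(act) < 2) next
        best <- NULL; bestr2 <- r2_max
        for (a in seq_along(act)) for (b in seq_along(act)) {
          if (a >= b) next
          va <- dos[, act[a]]; vb <- dos[, act[b]]
          r2 <- if (sd(va) == 0 || sd(vb) == 0) 0 else cor(va, vb)^2
          if (r2 > bestr2) { bestr2 <- r2; best <- c(act[a], act[b]) }
        }
        if (!is.null(best)) {
          pa <- pvals[best[1]]; pb <- pvals[best[2]]
          drop <- if (pa > pb) best[1] else if (pb > pa) best[2] else max(best)
          alive[drop] <- FALSE
          removed <- TRUE
        }
      }
    }
    if (!removed) break
  }
  which(alive)
}

# two-group log-rank by explicit risk-set accounting at each event time
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# tiny helpers for building panels in tests
make_panel <- function(dos, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                       info = NULL, ids = NULL) {
  m <- ncol(dos)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(m))
  v <- data.frame(variant_id = ids,
                  chrom = if (is.null(chrom)) rep("1", m) else chrom,
                  pos = if (is.null(pos)) seq_len(m) * 100L else pos,
                  ref = if (is.null(ref)) rep("A", m) else ref,
                  alt = if (is.null(alt)) rep("G", m) else alt,
                  info = if (is.null(info)) rep(1, m) else info,
                  stringsAsFactors = FALSE)
  dosage_panel(v, sprintf("ind%03d", seq_len(nrow(dos))), dos)
}

# harmonized-weights frame aligned to a panel, for direct scoring tests
make_weights <- function(panel, weight, p_value = NULL) {
  data.frame(variant_id = panel$variants$variant_id,
             p_value = if (is.null(p_value)) rep(0.5, length(weight)) else p_value,
             aligned_weight = weight,
             match_type = "direct",
             stringsAsFactors = FALSE)
}

small_cfg <- function(...) {
  args <- modifyList(list(n_variants = 200L, block_size = 20L,
                          within_block_rho = 0.5, n_discovery = 150L,
                          n_cases = 20L, n_relatives = 8L, n_controls = 25L,
                          prevalence = 0.1, seed = 42L), list(...))
  do.call(sim_config, args)
}
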