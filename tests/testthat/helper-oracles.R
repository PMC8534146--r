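# Naive double-loop reference implementations of every segregation statistic,
# written directly from the defining formulas and independent of the package
# internals. Inputs are plain matrices and label vectors.

# D_ij for domains given a per-bin domain index (1-based, NA = unassigned).
oracle_domain_contacts <- function(values, bin_dom) {
  doms <- sort(unique(bin_dom[!is.na(bin_dom)]))
  nd <- length(doms)
  D <- matrix(0, nd, nd)
  for (a in seq_len(nd)) {
    for (b in seq_len(nd)) {
      bi <- which(!is.na(bin_dom) & bin_dom == doms[a])
      bj <- which(!is.na(bin_dom) & bin_dom == doms[b])
      s <- 0
      for (x in bi) for (y in bj) s <- s + values[x, y]
      D[a, b] <- s / (length(bi) * length(bj))
    }
  }
  dimnames(D) <- list(doms, doms)
  D
}

# ORs via ordered same-type pairs over cross-type pairs (i in L, j in other).
oracle_ors <- function(values, bin_dom, dom_label, label) {
  D <- oracle_domain_contacts(values, bin_dom)
  doms <- as.integer(rownames(D))
  lab <- dom_label[doms]
  num <- 0
  den <- 0
  for (a in seq_along(doms)) {
    for (b in seq_along(doms)) {
      if (a == b) next
      if (lab[a] == label && lab[b] == label) num <- num + D[a, b]
      if (lab[a] == label && lab[b] != label) den <- den + D[a, b]
    }
  }
  num / den
}

oracle_drs <- function(values, bin_dom, dom_label) {
  D <- oracle_domain_contacts(values, bin_dom)
  doms <- as.integer(rownames(D))
  lab <- dom_label[doms]
  out <- numeric(length(doms))
  for (a in seq_along(doms)) {
    num <- 0
    den <- 0
    for (b in seq_along(doms)) {
      if (a == b) next
      if (lab[b] == lab[a]) num <- num + D[a, b] else den <- den + D[a, b]
    }
    out[a] <- if (den == 0) NA_real_ else num / den
  }
  names(out) <- doms
  out
}

# Rs(d): sum over i of both directions j = i - d and j = i + d.
oracle_rs <- function(values, bl, label, d) {
  other <- if (label == "F") "P" else "F"
  n <- nrow(values)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    if (is.na(bl[i]) || bl[i] != label) next
    for (j in c(i - d, i + d)) {
      if (j < 1 || j > n || is.na(bl[j])) next
      if (bl[j] == label) num <- num + values[i, j]
      if (bl[j] == other) den <- den + values[i, j]
    }
  }
  if (den == 0) NA_real_ else num / den
}

# TC10 at one offset: top ceiling(frac * n_d) entries, ties to lower index.
oracle_tc10_d <- function(values, bl, d, top_frac = 0.1) {
  n <- nrow(values)
  ent <- NULL
  for (i in seq_len(n - d)) {
    j <- i + d
    if (is.na(bl[i]) || is.na(bl[j])) next
    ent <- rbind(ent, data.frame(i = i, v = values[i, j],
                                 pair = paste0(sort(c(bl[i], bl[j])),
                                               collapse = "")))
  }
  if (is.null(ent)) return(NULL)
  k <- ceiling(top_frac * nrow(ent))
  ent <- ent[order(-ent$v, ent$i), ]
  sel <- ent[seq_len(k), ]
  if (any(sel$v == 0)) return(c(0, 0, 0))
  c(sum(sel$pair == "FF"), sum(sel$pair == "FP"), sum(sel$pair == "PP")) / k
}

oracle_cindex <- function(values, delta) {
  n <- nrow(values)
  na <- sum(delta == 1, na.rm = TRUE)
  nb <- sum(delta == 0, na.rm = TRUE)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(delta[i])) next
    sa <- 0
    sb <- 0
    for (j in seq_len(n)) {
      if (is.na(delta[j])) next
      if (delta[j] == 1) sa <- sa + values[i, j] else sb <- sb + values[i, j]
    }
    if (sa > 0 && sb > 0) out[i] <- log((sa / na) / (sb / nb))
  }
  out
}

oracle_mdi <- function(q) {
  n <- length(q)
  out <- rep(NA_real_, n)
  if (n < 3) return(out)
  for (i in 2:(n - 1)) {
    if (any(is.na(q[(i - 1):(i + 1)]))) next
    den <- (q[i - 1] + q[i] + q[i + 1]) / 3
    if (den == 0) next
    out[i] <- (q[i] - (q[i - 1] + q[i + 1]) / 2) / den
  }
  out
}

oracle_ror <- function(a, b) {
  nij <- 0
  nji <- 0
  for (k in seq_along(a)) {
    if (is.na(a[k]) || is.na(b[k])) next
    if (a[k] > b[k]) nij <- nij + 1
    if (a[k] < b[k]) nji <- nji + 1
  }
  log(nij / nji)
}
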