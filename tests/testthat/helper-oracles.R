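# Exhaustive single-gain parsimony oracle for Dollo loss counts.
#
# Independent of the package implementation: enumerates every gain node
# compatible with the presence set and, for each, every placement of losses
# on the nodes below it (via a bitmask subset sweep over leaf sets),
# returning the minimum number of losses that reproduces the observed
# presence/absence pattern exactly.

oracle_dollo_tables <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  stopifnot(ntip <= 16)
  edge <- tree$edge
  # leaf bitmask per node by simple fixpoint iteration (independent of the
  # package's postorder traversal)
  mask <- integer(nnode)
  mask[seq_len(ntip)] <- bitwShiftL(1L, seq_len(ntip) - 1L)
  repeat {
    new <- mask
    for (i in seq_len(nrow(edge))) {
      new[edge[i, 1]] <- bitwOr(new[edge[i, 1]], new[edge[i, 2]])
    }
    if (identical(new, mask)) break
    mask <- new
  }
  children <- split(edge[, 2], edge[, 1])
  # all nodes strictly below a node
  below <- function(v) {
    out <- integer(0)
    todo <- children[[as.character(v)]]
    while (length(todo) > 0L) {
      out <- c(out, todo)
      todo <- unlist(children[as.character(todo)], use.names = FALSE)
    }
    out
  }
  # for each candidate gain node: best[target_absent_mask + 1] = minimal
  # number of loss nodes whose leaf sets union to exactly target_absent_mask
  internal <- (ntip + 1L):nnode
  tabs <- vector("list", nnode)
  for (g in c(seq_len(ntip), internal)) {
    nb <- if (g <= ntip) integer(0) else below(g)
    k <- length(nb)
    n_sets <- bitwShiftL(1L, k)
    absent <- integer(n_sets)
    cnt <- integer(n_sets)
    if (k > 0L) {
      for (j in seq_len(k)) {
        bit <- bitwShiftL(1L, j - 1L)
        idx <- which(bitwAnd(seq_len(n_sets) - 1L, bit) > 0L)
        absent[idx] <- bitwOr(absent[idx - bit], mask[nb[j]])
        cnt[idx] <- cnt[idx - bit] + 1L
      }
    }
    best <- rep(NA_integer_, bitwShiftL(1L, ntip))
    o <- order(cnt)
    for (s in o) {
      key <- absent[s] + 1L
      if (is.na(best[key])) best[key] <- cnt[s]
    }
    tabs[[g]] <- best
  }
  list(mask = mask, tabs = tabs, ntip = ntip)
}

oracle_dollo <- function(tree, presence, tables = NULL) {
  if (is.null(tables)) tables <- oracle_dollo_tables(tree)
  tipidx <- match(presence, tree$tip.label)
  stopifnot(!anyNA(tipidx))
  pres_mask <- 0L
  for (i in tipidx) pres_mask <- bitwOr(pres_mask, bitwShiftL(1L, i - 1L))
  best <- NA_integer_
  for (g in seq_along(tables$tabs)) {
    gm <- tables$mask[g]
    if (bitwAnd(gm, pres_mask) != pres_mask) next  # gain must cover presence
    target <- bitwAnd(gm, bitwNot(pres_mask))
    v <- tables$tabs[[g]][target + 1L]
    if (!is.na(v) && (is.na(best) || v < best)) best <- v
  }
  best
}

# brute-force average ranks (ties as mean of occupied positions)
oracle_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    less + (eq + 1) / 2
  }, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x)
  ry <- oracle_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
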