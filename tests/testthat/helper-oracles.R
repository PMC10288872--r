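## Shared fixtures and independent oracles. Oracles are deliberately written
## from first principles (loops, enumeration, closed forms) and never call
## the implementation paths they check.

## a small rectangular section: block WM mask cut by a x-normal plane
make_strip_section <- function(ncol_ap = 10L, nrow_h = 4L, oversample = 1L) {
  shape <- c(4L, ncol_ap, nrow_h)
  wm <- cc_volume(array(1, shape))
  extract_section(wm, plane_spec(x = 1.5), oversample)
}

## a small, fast phantom for unit tests (acceptance uses the default one)
tiny_phantom <- function(seed = 7L, ...) {
  generate_phantom(phantom_spec(ap_extent = 35L, height = 6L, seed = seed,
                                ...))
}

## ground-truth band label aligned to a pipeline section
phantom_truth_for <- function(phantom, section) {
  gt <- phantom$ground_truth
  key <- function(m) paste(m[, 1], m[, 2])
  gt$band[match(key(section$coords), key(gt$section_coords))]
}

## brute-force flood fill (4/8-connectivity) over a coordinate set
oracle_components <- function(coords, diagonal = TRUE) {
  n <- nrow(coords)
  comp <- rep(NA_integer_, n)
  key <- paste(coords[, 1], coords[, 2])
  lut <- stats::setNames(seq_len(n), key)
  offs <- if (diagonal) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    comp[s] <- cid
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- sweep(offs, 2L, as.integer(coords[v, ]), "+")
      hits <- lut[paste(nb[, 1], nb[, 2])]
      for (w in hits[!is.na(hits)]) {
        if (is.na(comp[w])) {
          comp[w] <- cid
          stack <- c(stack, w)
        }
      }
    }
  }
  comp
}

## per-voxel 8-neighbour lists from scratch (coordinate scan, no package code)
oracle_neighbors <- function(coords) {
  n <- nrow(coords)
  key <- paste(coords[, 1], coords[, 2])
  lut <- stats::setNames(seq_len(n), key)
  lapply(seq_len(n), function(v) {
    nb <- integer(0)
    for (dy in -1:1) for (dz in -1:1) {
      if (dy == 0 && dz == 0) next
      w <- lut[paste(coords[v, 1] + dy, coords[v, 2] + dz)]
      if (!is.na(w)) nb <- c(nb, unname(w))
    }
    nb
  })
}

## brute-force regularized vote: per-voxel kernel evaluation with explicit
## neighbour scans and explicit tie rules
oracle_vote <- function(d, coords, self_weight = 1 / 2,
                        neighbor_weight = 1 / 12, neighbors = NULL) {
  n <- nrow(coords)
  L <- nrow(d)
  if (is.null(neighbors)) neighbors <- oracle_neighbors(coords)
  mass <- rowSums(d)
  labels <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    sc <- numeric(L)
    for (l in seq_len(L)) {
      nsum <- 0
      for (w in neighbors[[v]]) nsum <- nsum + d[l, w]
      sc[l] <- self_weight * d[l, v] + neighbor_weight * nsum
    }
    if (max(sc) > 0) {
      cand <- which(sc == max(sc))
      if (length(cand) > 1L) {
        cand <- cand[mass[cand] == max(mass[cand])]
      }
      labels[v] <- min(cand)
    }
  }
  labels
}

## hypergeometric point probability from binomial coefficients (no dhyper)
oracle_hyper <- function(a, m, n, k) {
  choose(m, a) * choose(n, k - a) / choose(m + n, k)
}

## two-sided Fisher p by full enumeration over margin-fixed tables
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- vapply(support, oracle_hyper, double(1), m = m, n = n, k = k)
  p0 <- oracle_hyper(a, m, n, k)
  min(1, sum(dens[dens <= p0 * (1 + 1e-7)]))
}

## definitional BH step-up: q(k) = min_{k' >= k} p(k') m / k'
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (k in seq_len(m)) {
    q[o[k]] <- min(1, min(p[o[k:m]] * m / (k:m)))
  }
  q
}
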