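# small construction helpers shared across test files

# bare model from an n x 3 coordinate matrix; one CA pseudo-atom per residue
mini_model <- function(xyz, chain = "A", resname = "ALA", atom = "CA",
                       element = "C", resno = NULL, type = "ATOM") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  at <- data.frame(
    serial = seq_len(n), atom = atom, resname = resname, chain = chain,
    resno = resno %||% seq_len(n), icode = "", x = xyz[, 1], y = xyz[, 2],
    z = xyz[, 3], occ = 1, alt = "", b = 0, element = element, type = type,
    stringsAsFactors = FALSE)
  structure_model(at)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_radii <- function(m) assign_radii(m)

# brute-force all-pairs neighbor oracle
brute_pairs <- function(xyz, cutoff) {
  d <- as.matrix(dist(xyz))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2],
             distance = d[cbind(idx[, 1], idx[, 2])])
}

# exhaustive global-alignment score by recursive enumeration (small inputs)
enum_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# random planted-contact spec for recovery tests
random_contact_spec <- function(seed) {
  set.seed(seed)
  spec <- list()
  for (k in seq_len(sample(0:2, 1)))
    spec[[length(spec) + 1]] <- list(category = "hydrogen_bond",
                                     distance = runif(1, 2.6, 3.4))
  if (runif(1) < 0.7) {
    bid <- runif(1) < 0.5
    spec[[length(spec) + 1]] <- list(category = "salt_bridge",
                                     distance = runif(1, if (bid) 3.4 else 3.0,
                                                      3.9),
                                     bidentate = bid)
  }
  for (k in seq_len(sample(0:2, 1)))
    spec[[length(spec) + 1]] <- list(category = "vdw",
                                     distance = runif(1, 3.6, 3.95))
  if (runif(1) < 0.7)
    spec[[length(spec) + 1]] <- list(category = "water_bridge",
                                     d_a = runif(1, 2.6, 3.3),
                                     d_b = runif(1, 2.6, 3.3))
  spec
}

# expected counts for a spec (bidentate salt bridges give two records)
spec_counts <- function(spec) {
  n <- c(hydrogen_bond = 0L, salt_bridge = 0L, vdw = 0L, water_bridge = 0L)
  for (pc in spec) {
    inc <- if (pc$category == "salt_bridge" && isTRUE(pc$bidentate)) 2L else 1L
    n[pc$category] <- n[pc$category] + inc
  }
  n
}
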