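#' @title Homolog cross-reactivity and glycosylation analysis
#' @description Rationalizes differential antibody binding between antigen
#'   homologs (e.g. PD-L1 vs PD-L2): structure-based pairing of homolog
#'   residues, grafting of a homolog side chain into the antibody complex
#'   by superposition, steric-clash scanning, and mapping of
#'   N-glycosylation sequons relative to the epitope.
#' @name crossreact_glyco
NULL

aa_alphabet <- function() c(AA1, "X")

#' Global sequence alignment (Needleman-Wunsch, linear gaps)
#'
#' Optimal global alignment under match/mismatch/gap scores with a linear
#' gap penalty. Tie-breaking in the traceback is deterministic: diagonal
#' preferred, then the gap consuming `seq_a`.
#'
#' @param seq_a,seq_b one-letter amino-acid strings
#' @param match,mismatch,gap scores (defaults 1 / -1 / -2)
#' @return object of class `pair_alignment`: list(aligned_a, aligned_b,
#'   score, pairs data.frame(i, j) of aligned positions); attribute
#'   `identity` = identical pairs / aligned pairs
#' @export
needleman_wunsch <- function(seq_a, seq_b, match = 1, mismatch = -1,
                             gap = -2) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  bad <- setdiff(c(a, b), aa_alphabet())
  if (length(bad))
    stop("illegal residue character(s): ", paste(bad, collapse = ", "))
  n <- length(a); m <- length(b)
  f <- matrix(0, n + 1, m + 1)
  f[, 1] <- gap * (0:n); f[1, ] <- gap * (0:m)
  if (n > 0 && m > 0) {
    sub <- outer(a, b, function(x, y) ifelse(x == y, match, mismatch))
    for (i in 1:n) for (j in 1:m) {
      f[i + 1, j + 1] <- max(f[i, j] + sub[i, j],
                             f[i, j + 1] + gap,
                             f[i + 1, j] + gap)
    }
  }
  ## traceback, preferring diagonal then up (gap in seq_b)
  i <- n; j <- m
  al_a <- character(); al_b <- character()
  pi <- integer(); pj <- integer()
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && f[i + 1, j + 1] == f[i, j] + sub[i, j]) {
      al_a <- c(a[i], al_a); al_b <- c(b[j], al_b)
      pi <- c(i, pi); pj <- c(j, pj)
      i <- i - 1; j <- j - 1
    } else if (i > 0 && f[i + 1, j + 1] == f[i, j + 1] + gap) {
      al_a <- c(a[i], al_a); al_b <- c("-", al_b)
      i <- i - 1
    } else {
      al_a <- c("-", al_a); al_b <- c(b[j], al_b)
      j <- j - 1
    }
  }
  pairs <- data.frame(i = pi, j = pj)
  out <- list(aligned_a = paste(al_a, collapse = ""),
              aligned_b = paste(al_b, collapse = ""),
              score = f[n + 1, m + 1], pairs = pairs)
  class(out) <- "pair_alignment"
  attr(out, "identity") <- if (nrow(pairs) == 0) 0 else
    mean(a[pairs$i] == b[pairs$j])
  out
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("pair_alignment: score %g, %d aligned pairs, identity %.0f%%\n",
              x$score, nrow(x$pairs), 100 * (attr(x, "identity") %||% NA)))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

## longest increasing subsequence (indices) - enforces sequence order
lis_idx <- function(v) {
  n <- length(v)
  if (n == 0) return(integer())
  best <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    for (l in seq_len(k - 1)) {
      if (v[l] < v[k] && best[l] + 1L > best[k]) {
        best[k] <- best[l] + 1L; prev[k] <- l
      }
    }
  }
  k <- which.max(best)
  out <- integer()
  while (!is.na(k)) { out <- c(k, out); k <- prev[k] }
  out
}

#' Structure-based residue pairing of two homologs
#'
#' Iterates Kabsch superposition on the current CA pair set, then re-pairs
#' mutually nearest CA atoms within `pair_cutoff`, keeping only
#' sequence-order-preserving pairs, until the pair set is stable (at most
#' `max_iter` rounds). Seeded from a sequence alignment unless a seed
#' pairing is given.
#'
#' @param model_a,model_b structure_model (single protein chain each, or
#'   the first non-water chain is used)
#' @param seed optional data.frame(i, j) of seed residue-index pairs
#'   (indices into each chain's residue list); default: Needleman-Wunsch
#'   pairs of the chain sequences
#' @param pair_cutoff CA-CA pairing cutoff in Angstrom (default 3.5)
#' @param max_iter iteration cap (default 20)
#' @return object of class `structural_alignment`: pairs data.frame
#'   (resno_a, icode_a, resname_a, resno_b, icode_b, resname_b,
#'   ca_distance), fit (superposition mapping a onto b), n_iter, converged
#' @export
structural_alignment <- function(model_a, model_b, seed = NULL,
                                 pair_cutoff = 3.5, max_iter = 20) {
  ca <- function(m) {
    prot <- m$atoms[m$atoms$resname != "HOH" & m$atoms$atom == "CA", ,
                    drop = FALSE]
    prot[prot$chain == prot$chain[1], , drop = FALSE]
  }
  a <- ca(model_a); b <- ca(model_b)
  if (is.null(seed)) {
    nw <- needleman_wunsch(paste(aa_three_to_one(a$resname), collapse = ""),
                           paste(aa_three_to_one(b$resname), collapse = ""))
    seed <- nw$pairs
  }
  if (nrow(seed) < 3) stop("seed pairing has fewer than 3 pairs")
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  cur <- seed
  fit <- NULL
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    fit <- kabsch(xa[cur$i, , drop = FALSE], xb[cur$j, , drop = FALSE])
    ta <- sweep(xa %*% fit$rotation, 2, fit$translation, "+")
    ## mutual nearest neighbours within cutoff
    d2 <- outer(rowSums(ta^2), rowSums(xb^2), "+") - 2 * ta %*% t(xb)
    d2[d2 < 0] <- 0
    nn_ab <- apply(d2, 1, which.min)
    nn_ba <- apply(d2, 2, which.min)
    ii <- seq_len(nrow(ta))
    mutual <- nn_ba[nn_ab] == ii &
      sqrt(d2[cbind(ii, nn_ab)]) <= pair_cutoff
    new <- data.frame(i = ii[mutual], j = nn_ab[mutual])
    new <- new[order(new$i), , drop = FALSE]
    new <- new[lis_idx(new$j), , drop = FALSE]  # keep topology-consistent
    if (nrow(new) < 3) stop("structural pairing collapsed below 3 pairs")
    if (nrow(new) == nrow(cur) && all(new$i == cur$i) && all(new$j == cur$j)) {
      converged <- TRUE
      break
    }
    cur <- new
  }
  if (!converged && n_iter >= max_iter)
    warning("pairing did not stabilize within ", max_iter, " iterations")
  fit <- kabsch(xa[cur$i, , drop = FALSE], xb[cur$j, , drop = FALSE])
  ta <- sweep(xa[cur$i, , drop = FALSE] %*% fit$rotation, 2,
              fit$translation, "+")
  dist <- sqrt(rowSums((ta - xb[cur$j, , drop = FALSE])^2))
  pairs <- data.frame(
    resno_a = a$resno[cur$i], icode_a = a$icode[cur$i],
    resname_a = a$resname[cur$i],
    resno_b = b$resno[cur$j], icode_b = b$icode[cur$j],
    resname_b = b$resname[cur$j],
    ca_distance = dist, stringsAsFactors = FALSE)
  out <- list(pairs = pairs, fit = fit, n_iter = n_iter,
              converged = converged)
  class(out) <- "structural_alignment"
  out
}

#' @export
print.structural_alignment <- function(x, ...) {
  cat(sprintf("structural_alignment: %d pairs, rmsd %.2f A, %d iteration(s)%s\n",
              nrow(x$pairs), x$fit$rmsd, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Steric-clash scan of a grafted homolog side chain
#'
#' Superposes the homolog onto the complexed antigen using the
#' structural-alignment transform and reports heavy-atom clashes between
#' the target residue's side chain (the homolog's own coordinates, no
#' rotamer rebuilding) and the binder atoms: pairs with
#' d < r_i + r_j - overlap_min.
#'
#' @param complex structure_model of the antigen-binder complex (roles and
#'   radii assigned)
#' @param homolog structure_model of the homolog antigen (radii assigned)
#' @param alignment [structural_alignment()] of `homolog` onto the
#'   complex's antigen
#' @param target_residue list(chain =, resno =, icode = "") naming the
#'   homolog residue to graft
#' @param overlap_min vdW overlap threshold in Angstrom (default 0.4)
#' @param side_binder selection spec for the binder side
#' @return object of class `clash_report`: grafted_residue, clashes
#'   data.frame(graft_atom, partner_chain, partner_resno, partner_resname,
#'   partner_atom, distance, overlap), count, max_overlap
#' @export
graft_clash_scan <- function(complex, homolog, alignment, target_residue,
                             overlap_min = 0.4,
                             side_binder = list(role = c("heavy", "light"))) {
  icode <- target_residue$icode %||% ""
  hat <- homolog$atoms
  sel <- hat$chain == target_residue$chain &
    hat$resno == target_residue$resno & hat$icode == icode
  if (!any(sel)) stop("target residue not found in homolog")
  if (!target_residue$resno %in% alignment$pairs$resno_a)
    warning("target residue is in an unpaired region; ",
            "scanning with the global transform")
  if (is.null(hat$radius) || is.null(complex$atoms$radius))
    stop("radii not assigned on complex and/or homolog")
  graft <- hat[sel & !(hat$atom %in% c("N", "CA", "C", "O", "OXT")), ,
               drop = FALSE]
  if (nrow(graft) == 0) stop("target residue has no side-chain atoms")
  gx <- as.matrix(graft[, c("x", "y", "z")]) %*% alignment$fit$rotation
  gx <- sweep(gx, 2, alignment$fit$translation, "+")
  binder <- side_model(complex, side_binder)
  bat <- binder$atoms
  bx <- as.matrix(bat[, c("x", "y", "z")])
  out <- list(); n <- 0L
  for (k in seq_len(nrow(graft))) {
    d <- sqrt(rowSums(sweep(bx, 2, gx[k, ])^2))
    lim <- graft$radius[k] + bat$radius - overlap_min
    hit <- which(d < lim)
    if (!length(hit)) next
    n <- n + 1L
    out[[n]] <- data.frame(
      graft_atom = graft$atom[k],
      partner_chain = bat$chain[hit], partner_resno = bat$resno[hit],
      partner_resname = bat$resname[hit], partner_atom = bat$atom[hit],
      distance = d[hit],
      overlap = graft$radius[k] + bat$radius[hit] - d[hit],
      stringsAsFactors = FALSE)
  }
  clashes <- if (n) do.call(rbind, out) else
    data.frame(graft_atom = character(), partner_chain = character(),
               partner_resno = integer(), partner_resname = character(),
               partner_atom = character(), distance = numeric(),
               overlap = numeric())
  rep <- list(grafted_residue = target_residue, clashes = clashes,
              count = nrow(clashes),
              max_overlap = if (nrow(clashes)) max(clashes$overlap) else 0,
              overlap_min = overlap_min)
  class(rep) <- "clash_report"
  rep
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("clash_report: %d clash(es), max overlap %.2f A (threshold %.2f A)\n",
              x$count, x$max_overlap, x$overlap_min))
  if (x$count)
    cat("  partners:",
        paste(unique(sprintf("%s_%s%d", x$clashes$partner_chain,
                             aa_three_to_one(x$clashes$partner_resname),
                             x$clashes$partner_resno)), collapse = " "), "\n")
  invisible(x)
}

#' Find N-glycosylation sequons in a sequence
#'
#' All N-X-[S/T] motifs with X != P, reported in author numbering via
#' `numbering_offset` (position = string index + offset).
#'
#' @param sequence one-letter amino-acid string
#' @param numbering_offset added to 1-based string positions
#' @return data.frame(position, triplet)
#' @export
find_sequons <- function(sequence, numbering_offset = 0L) {
  s <- toupper(sequence)
  hits <- gregexpr("N(?=[^P][ST])", s, perl = TRUE)[[1]]
  if (hits[1] == -1)
    return(data.frame(position = integer(), triplet = character()))
  data.frame(position = as.integer(hits) + numbering_offset,
             triplet = substring(s, hits, hits + 2),
             stringsAsFactors = FALSE)
}

#' Distance of glycosylation sites to an epitope
#'
#' Minimum heavy-atom distance from each glycosylation Asn's side chain to
#' any atom of an epitope residue. Sites farther than `threshold` (or
#' absent from the crystallized construct) are flagged independent of
#' antibody binding.
#'
#' @param model structure_model (antigen role assigned)
#' @param glyco_positions integer vector of Asn author residue numbers
#' @param epitope [epitope_set()] on the same antigen
#' @param threshold independence distance in Angstrom (default 10)
#' @return data.frame(position, present, min_distance_A, independent)
#' @export
glyco_epitope_distance <- function(model, glyco_positions, epitope,
                                   threshold = 10) {
  ant <- select_atoms(model, role = "antigen")
  ant <- select_atoms(ant, chain = ant$atoms$chain[1])
  epi <- epitope$residues
  em <- model$atoms[paste(model$atoms$chain, model$atoms$resno,
                          model$atoms$icode) %in%
                      paste(epi$chain, epi$resno, epi$icode), , drop = FALSE]
  ex <- as.matrix(em[, c("x", "y", "z")])
  out <- lapply(glyco_positions, function(p) {
    res <- ant$atoms[ant$atoms$resno == p & ant$atoms$resname == "ASN", ,
                     drop = FALSE]
    side <- res[!(res$atom %in% c("N", "CA", "C", "O", "OXT")), ,
                drop = FALSE]
    if (nrow(side) == 0)
      return(data.frame(position = p, present = FALSE,
                        min_distance_A = NA_real_, independent = TRUE))
    dmin <- min(apply(as.matrix(side[, c("x", "y", "z")]), 1, function(v)
      min(sqrt(rowSums(sweep(ex, 2, v)^2)))))
    data.frame(position = p, present = TRUE, min_distance_A = dmin,
               independent = dmin > threshold)
  })
  do.call(rbind, out)
}
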