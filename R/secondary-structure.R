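# Torsion angle (degrees) of four points, standard IUPAC sign convention.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  m1 <- c(
    n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
    n1[1] * b2[2] - n1[2] * b2[1]
  )
  b2n <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / b2n
  atan2(y, x) * 180 / pi
}

# Kabsch-Sander coupling constant: 0.084 e^2 * 332 kcal/(mol A)
.KS_Q <- 0.084 * 332
.HBOND_CUTOFF <- -0.5

#' Kabsch-Sander hydrogen-bond energy between two residues
#'
#' Electrostatic model of a backbone N-H...O=C hydrogen bond:
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol, with the
#' amide hydrogen placed 1 Angstrom from the donor nitrogen along the C=O
#' bond direction of the preceding residue (the classic DSSP construction).
#' An energy below -0.5 kcal/mol counts as a hydrogen bond.
#'
#' @param donor coordinate matrix of the donor residue (rownames are atom
#'   names; needs `N`).
#' @param acceptor coordinate matrix of the acceptor residue (needs `C` and
#'   `O`).
#' @param donorPrev coordinate matrix of the residue preceding the donor in
#'   its chain (needs `C` and `O`), used to place the amide hydrogen; `NULL`
#'   for chain-terminal donors.
#' @param donorResid three-letter residue name of the donor; prolines have no
#'   amide hydrogen and never donate.
#' @return Energy in kcal/mol, or `NA` (the no-bond sentinel) when the
#'   geometry cannot be evaluated (missing atoms, proline donor, terminal
#'   donor).
#' @export
hbondEnergy <- function(donor, acceptor, donorPrev = NULL,
                        donorResid = "ALA") {
  if (donorResid == "PRO") {
    return(NA_real_)
  }
  if (is.null(donorPrev)) {
    return(NA_real_)
  }
  need <- function(m, atoms) all(atoms %in% rownames(m))
  if (!need(donor, "N") || !need(acceptor, c("C", "O")) ||
    !need(donorPrev, c("C", "O"))) {
    return(NA_real_)
  }
  n <- donor["N", ]
  co <- donorPrev["C", ] - donorPrev["O", ]
  h <- n + co / sqrt(sum(co^2))
  cc <- acceptor["C", ]
  o <- acceptor["O", ]
  dist <- function(a, b) sqrt(sum((a - b)^2))
  rON <- dist(o, n)
  rCH <- dist(cc, h)
  rOH <- dist(o, h)
  rCN <- dist(cc, n)
  if (min(rON, rCH, rOH, rCN) < 0.5) {
    return(-9.9) # clashing atoms: treat as a (strong) bond like DSSP does
  }
  .KS_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

# Per-chain bookkeeping for the DSSP variant: for every amino-acid residue,
# its coordinates, chain-local position, and whether it is peptide-bonded to
# its chain predecessor (C-N distance < 2.5 A).
.amino_context <- function(model) {
  rt <- residueTable(model)
  ridx <- .residue_index(model)
  at <- model@atoms
  keep <- which(rt$kind == "amino")
  n <- length(keep)
  coords <- vector("list", n)
  for (i in seq_len(n)) {
    coords[[i]] <- .residue_coords(at, ridx[[keep[i]]])
  }
  chain <- rt$chain[keep]
  resid <- rt$resid[keep]
  key <- rt$key[keep]
  bonded_prev <- rep(FALSE, n)
  for (i in seq_len(n)[-1]) {
    if (chain[i] != chain[i - 1]) next
    ci <- coords[[i - 1]]
    ni <- coords[[i]]
    if (!("C" %in% rownames(ci)) || !("N" %in% rownames(ni))) next
    if (sqrt(sum((ci["C", ] - ni["N", ])^2)) < 2.5) bonded_prev[i] <- TRUE
  }
  list(
    n = n, coords = coords, chain = chain, resid = resid, key = key,
    bonded_prev = bonded_prev
  )
}

# n x n logical matrix: hb[d, a] TRUE when residue d's N-H donates to
# residue a's C=O. Pairs are prefiltered by CA distance < 9 A.
.hbond_matrix <- function(ctx) {
  n <- ctx$n
  hb <- matrix(FALSE, n, n)
  if (n < 2) {
    return(hb)
  }
  ca <- t(vapply(ctx$coords, function(m) {
    if ("CA" %in% rownames(m)) m["CA", ] else c(NA_real_, NA_real_, NA_real_)
  }, numeric(3)))
  d2 <- as.matrix(stats::dist(ca))^2
  for (d in seq_len(n)) {
    if (!ctx$bonded_prev[d]) next
    prev <- ctx$coords[[d - 1]]
    for (a in seq_len(n)) {
      if (a == d) next
      if (ctx$chain[a] == ctx$chain[d] && abs(a - d) < 2) next
      if (!is.na(d2[d, a]) && d2[d, a] > 81) next
      e <- hbondEnergy(ctx$coords[[d]], ctx$coords[[a]],
        donorPrev = prev, donorResid = ctx$resid[d]
      )
      if (!is.na(e) && e < .HBOND_CUTOFF) hb[d, a] <- TRUE
    }
  }
  hb
}

# residues helix-labeled by the two-consecutive-(i -> i+4)-turns rule
.detect_helix <- function(ctx, hb) {
  n <- ctx$n
  out <- rep(FALSE, n)
  contig <- function(i, j) {
    # i..j consecutive, same chain, all peptide-bonded
    j <= n && ctx$chain[i] == ctx$chain[j] &&
      all(ctx$bonded_prev[(i + 1):j])
  }
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i + 4 <= n && contig(i, i + 4) && hb[i + 4, i]) turn4[i] <- TRUE
  }
  for (i in seq_len(n)) {
    if (i + 1 <= n && turn4[i] && turn4[i + 1]) {
      out[(i + 1):(i + 4)] <- TRUE
    }
  }
  out
}

# residues participating in at least one Kabsch-Sander bridge; the parallel
# and antiparallel bond patterns are both accepted and treated identically
# (no ladder direction or sheet topology is recorded)
.detect_sheet <- function(ctx, hb) {
  n <- ctx$n
  out <- rep(FALSE, n)
  has_prev <- ctx$bonded_prev
  has_next <- c(ctx$bonded_prev[-1], FALSE)
  HB <- function(d, a) {
    d >= 1 && d <= n && a >= 1 && a <= n && hb[d, a]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (ctx$chain[i] == ctx$chain[j] && j - i < 3) next
      par <- (has_prev[i] && HB(j, i - 1) && has_next[i] && HB(i + 1, j)) ||
        (has_prev[j] && HB(i, j - 1) && has_next[j] && HB(j + 1, i))
      anti <- (HB(j, i) && HB(i, j)) ||
        (has_prev[i] && has_next[i] && has_prev[j] && has_next[j] &&
          HB(j + 1, i - 1) && HB(i + 1, j - 1))
      if (par || anti) {
        out[i] <- TRUE
        out[j] <- TRUE
      }
    }
  }
  out
}

# phi/psi (degrees) for every amino residue in context; NA at chain termini
.phi_psi <- function(ctx) {
  n <- ctx$n
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  has_next <- c(ctx$bonded_prev[-1], FALSE)
  for (i in seq_len(n)) {
    m <- ctx$coords[[i]]
    if (!all(c("N", "CA", "C") %in% rownames(m))) next
    if (ctx$bonded_prev[i]) {
      pm <- ctx$coords[[i - 1]]
      if ("C" %in% rownames(pm)) {
        phi[i] <- .dihedral(pm["C", ], m["N", ], m["CA", ], m["C", ])
      }
    }
    if (has_next[i]) {
      nm <- ctx$coords[[i + 1]]
      if ("N" %in% rownames(nm)) {
        psi[i] <- .dihedral(m["N", ], m["CA", ], m["C", ], nm["N", ])
      }
    }
  }
  list(phi = phi, psi = psi)
}

.in_helix_window <- function(phi, psi, win) {
  !is.na(phi) && !is.na(psi) &&
    phi > win$helix_phi[1] && phi < win$helix_phi[2] &&
    psi > win$helix_psi[1] && psi < win$helix_psi[2]
}

.in_sheet_window <- function(phi, psi, win) {
  !is.na(phi) && !is.na(psi) &&
    phi > win$sheet_phi[1] && phi < win$sheet_phi[2] &&
    (psi > win$sheet_psi_hi[1] || psi < win$sheet_psi_lo[2])
}

#' Ramachandran windows used by the torsion-angle extension
#'
#' Fixed phi/psi regions (degrees) for the alpha-helical and beta-strand
#' basins, chosen from standard STRIDE/Richardson-style Ramachandran regions.
#'
#' @return list with components `helix_phi`, `helix_psi`, `sheet_phi`,
#'   `sheet_psi_hi` (upper basin) and `sheet_psi_lo` (wrapped lower basin).
#' @export
ramachandranWindows <- function() {
  list(
    helix_phi = c(-100, -30), helix_psi = c(-80, -5),
    sheet_phi = c(-180, -45), sheet_psi_hi = c(90, 180),
    sheet_psi_lo = c(-180, -150)
  )
}

#' Extend secondary-structure labels by Ramachandran profile
#'
#' Iteratively relabels an unassigned residue that is immediately
#' peptide-bonded to a helix (resp. sheet) residue as helix (resp. sheet)
#' when its (phi, psi) pair falls in the corresponding Ramachandran window,
#' until a fixed point is reached. Extension is monotone: it only converts
#' unassigned residues and never removes or changes an existing label.
#' Residues lacking phi or psi (chain termini) are never extended.
#'
#' @param labels named character vector of per-residue classes as produced by
#'   [assignSecondaryStructure()] (names are residue keys).
#' @param model the [StructuralModel-class] the labels belong to.
#' @param windows Ramachandran windows, see [ramachandranWindows()].
#' @return The extended label vector.
#' @export
extendByRamachandran <- function(labels, model,
                                 windows = ramachandranWindows()) {
  ctx <- .amino_context(model)
  if (ctx$n == 0) {
    return(labels)
  }
  tor <- .phi_psi(ctx)
  lab <- labels[ctx$key]
  has_next <- c(ctx$bonded_prev[-1], FALSE)
  repeat {
    changed <- FALSE
    for (i in seq_len(ctx$n)) {
      if (lab[i] != "unassigned") next
      nb <- character(0)
      if (ctx$bonded_prev[i]) nb <- c(nb, lab[i - 1])
      if (has_next[i]) nb <- c(nb, lab[i + 1])
      if ("helix" %in% nb &&
        .in_helix_window(tor$phi[i], tor$psi[i], windows)) {
        lab[i] <- "helix"
        changed <- TRUE
      } else if ("sheet" %in% nb &&
        .in_sheet_window(tor$phi[i], tor$psi[i], windows)) {
        lab[i] <- "sheet"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels[ctx$key] <- lab
  labels
}

#' Assign per-residue secondary-structure labels
#'
#' Produces one class per residue out of helix, sheet, nucleotide and
#' unassigned:
#' nucleotide residues are always `nucleotide`; author helix/sheet ranges are
#' applied; a DSSP-variant hydrogen-bond analysis detects alpha-helices
#' (two consecutive i to i+4 bonds) and beta-bridge residues (parallel and
#' antiparallel Kabsch-Sander bridge patterns accepted identically, without
#' recording strand direction); detected labels fill gaps in the author
#' annotation with author classes winning conflicts; finally labels are
#' extended along the chain by [extendByRamachandran()]. Chains of fewer than
#' 3 amino acids are left unassigned.
#'
#' @param model a [StructuralModel-class].
#' @param extend logical; apply the torsion-angle extension (default TRUE).
#' @param windows Ramachandran windows for the extension.
#' @return Named character vector (names are residue keys in model order)
#'   with values in [VOXEL_CLASSES].
#' @export
assignSecondaryStructure <- function(model, extend = TRUE,
                                     windows = ramachandranWindows()) {
  rt <- residueTable(model)
  labels <- stats::setNames(rep("unassigned", nrow(rt)), rt$key)
  labels[rt$kind == "nucleotide"] <- "nucleotide"

  ctx <- .amino_context(model)
  if (ctx$n >= 3) {
    hb <- .hbond_matrix(ctx)
    helix <- .detect_helix(ctx, hb)
    sheet <- .detect_sheet(ctx, hb)
    chain_len <- table(ctx$chain)
    ok_chain <- ctx$chain %in% names(chain_len)[chain_len >= 3]
    labels[ctx$key[helix & ok_chain]] <- "helix"
    labels[ctx$key[sheet & !helix & ok_chain]] <- "sheet"
  }

  # author annotations override detected labels on conflict
  ss <- model@authorSS
  if (nrow(ss) > 0) {
    for (i in seq_len(nrow(ss))) {
      sel <- rt$chain == ss$chain[i] & rt$kind == "amino" &
        rt$resno >= ss$start[i] & rt$resno <= ss$end[i]
      labels[rt$key[sel]] <- ss$class[i]
    }
  }

  if (extend) labels <- extendByRamachandran(labels, model, windows)
  labels
}
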