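.AMINO3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)
.NUC3 <- c("A", "U", "G", "C", "T", "I", "DA", "DT", "DG", "DC", "DU", "DI")

.residue_kind <- function(resid, eletys) {
  if (resid %in% .AMINO3) {
    return("amino")
  }
  if (resid %in% .NUC3) {
    return("nucleotide")
  }
  # fall back on backbone atom content for modified residues
  if (any(c("C4'", "O5'", "O3'") %in% eletys) && "P" %in% eletys) {
    return("nucleotide")
  }
  if (all(c("N", "CA", "C") %in% eletys)) {
    return("amino")
  }
  "other"
}

# keep, per (chain, resno, insert, atom name), the highest-occupancy altloc;
# ties resolved to the first occurrence. Residues are ordered by chain and
# sequence number; atoms keep their file order within a residue.
.resolve_altloc <- function(at) {
  at$.row <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$occ, at$.row, method = "radix")
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$chain, at$resno, at$insert, at$.row, method = "radix"), ,
    drop = FALSE]
  at$.row <- NULL
  at
}

.finish_model <- function(at, ss) {
  at$insert[is.na(at$insert)] <- ""
  at$occ[is.na(at$occ)] <- 1
  at <- .resolve_altloc(at)
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  kinds <- vapply(
    split(seq_len(nrow(at)), factor(key, levels = unique(key))),
    function(ix) .residue_kind(at$resid[ix[1]], at$elety[ix]), ""
  )
  at$kind <- kinds[match(key, unique(key))]
  at <- at[at$kind != "other" | at$resid != "HOH", , drop = FALSE]
  if (nrow(at) == 0 || !any(at$kind %in% c("amino", "nucleotide"))) {
    stop("empty model: no polymer residues found")
  }
  rownames(at) <- NULL
  if (is.null(ss) || nrow(ss) == 0) {
    ss <- data.frame(
      chain = character(), start = integer(), end = integer(),
      class = character(), stringsAsFactors = FALSE
    )
  }
  new("StructuralModel",
    atoms = at[, c(
      "chain", "resno", "insert", "resid", "elety",
      "x", "y", "z", "kind"
    )],
    authorSS = ss
  )
}

.ss_from_bio3d <- function(pdb) {
  rows <- list()
  h <- pdb$helix
  if (!is.null(h) && length(h$start) > 0) {
    rows[[1]] <- data.frame(
      chain = as.character(h$chain),
      start = as.integer(h$start), end = as.integer(h$end),
      class = "helix", stringsAsFactors = FALSE
    )
  }
  s <- pdb$sheet
  if (!is.null(s) && length(s$start) > 0) {
    rows[[2]] <- data.frame(
      chain = as.character(s$chain),
      start = as.integer(s$start), end = as.integer(s$end),
      class = "sheet", stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

.read_model_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  at <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    insert = as.character(a$insert), resid = as.character(a$resid),
    elety = as.character(a$elety), x = a$x, y = a$y, z = a$z,
    occ = as.numeric(a$o), stringsAsFactors = FALSE
  )
  .finish_model(at, .ss_from_bio3d(pdb))
}

.read_model_cif <- function(path) {
  # read.cif prints a beta-quality notice; the parse itself is fine here
  pdb <- suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  a <- pdb$atom
  at <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    insert = as.character(a$insert), resid = as.character(a$resid),
    elety = as.character(a$elety), x = a$x, y = a$y, z = a$z,
    occ = as.numeric(a$o), stringsAsFactors = FALSE
  )
  ss <- .ss_from_bio3d(pdb)
  if (is.null(ss)) ss <- .ss_from_cif_text(path)
  .finish_model(at, ss)
}

# minimal scan of struct_conf / struct_sheet_range categories for author
# secondary structure in mmCIF files where the coordinate reader drops them
.ss_from_cif_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parse_cat <- function(cat, class, chaincol, startcol, endcol, typecol) {
    hdr <- grep(paste0("^_", cat, "\\."), lines)
    if (length(hdr) == 0) {
      return(NULL)
    }
    fields <- sub(paste0("^_", cat, "\\."), "", trimws(lines[hdr]))
    fields <- sub("\\s.*$", "", fields)
    body <- lines[(max(hdr) + 1):length(lines)]
    stopat <- which(grepl("^(#|loop_|_)", body))[1]
    if (!is.na(stopat)) body <- body[seq_len(stopat - 1)]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0) {
      return(NULL)
    }
    toks <- lapply(strsplit(trimws(body), "\\s+"), identity)
    toks <- toks[vapply(toks, length, 1L) == length(fields)]
    if (length(toks) == 0) {
      return(NULL)
    }
    m <- do.call(rbind, toks)
    colnames(m) <- fields
    need <- c(chaincol, startcol, endcol)
    if (!all(need %in% fields)) {
      return(NULL)
    }
    keep <- rep(TRUE, nrow(m))
    if (!is.null(typecol) && typecol %in% fields) {
      keep <- grepl("^HELX", m[, typecol])
    }
    if (!any(keep)) {
      return(NULL)
    }
    data.frame(
      chain = m[keep, chaincol], start = as.integer(m[keep, startcol]),
      end = as.integer(m[keep, endcol]), class = class,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    parse_cat(
      "struct_conf", "helix", "beg_auth_asym_id",
      "beg_auth_seq_id", "end_auth_seq_id", "conf_type_id"
    ),
    parse_cat(
      "struct_sheet_range", "sheet", "beg_auth_asym_id",
      "beg_auth_seq_id", "end_auth_seq_id", NULL
    )
  )
}

# namespace-agnostic xpath fragments (PDBML files use a PDBx prefix whose
# URI varies by schema version)
.ln <- function(tag) sprintf("*[local-name()='%s']", tag)

.read_model_pdbml <- function(path) {
  doc <- xml2::read_xml(path)
  sites <- xml2::xml_find_all(
    doc, paste0("//", .ln("atom_siteCategory"), "/", .ln("atom_site"))
  )
  if (length(sites) == 0) stop("unparseable PDBML: no atom_site records")
  get <- function(node, tag) {
    xml2::xml_text(xml2::xml_find_first(node, .ln(tag)))
  }
  n <- length(sites)
  chain <- character(n)
  resno <- integer(n)
  insert <- character(n)
  resid <- character(n)
  elety <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  occ <- numeric(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    s <- sites[[i]]
    grp <- get(s, "group_PDB")
    if (!grp %in% c("ATOM", "HETATM")) next
    chain[i] <- get(s, "auth_asym_id")
    resno[i] <- suppressWarnings(as.integer(get(s, "auth_seq_id")))
    ic <- get(s, "pdbx_PDB_ins_code")
    insert[i] <- ifelse(is.na(ic), "", ic)
    resid[i] <- get(s, "auth_comp_id")
    elety[i] <- get(s, "auth_atom_id")
    xyz[i, ] <- as.numeric(c(get(s, "Cartn_x"), get(s, "Cartn_y"),
      get(s, "Cartn_z")))
    oc <- suppressWarnings(as.numeric(get(s, "occupancy")))
    occ[i] <- ifelse(is.na(oc), 1, oc)
    keep[i] <- TRUE
  }
  at <- data.frame(
    chain = chain, resno = resno, insert = insert, resid = resid,
    elety = elety, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = occ,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  ss <- rbind(
    .pdbml_ss(doc, "struct_confCategory", "struct_conf", "helix", TRUE),
    .pdbml_ss(
      doc, "struct_sheet_rangeCategory", "struct_sheet_range",
      "sheet", FALSE
    )
  )
  .finish_model(at, ss)
}

.pdbml_ss <- function(doc, cat, rec, class, helix_only) {
  nodes <- xml2::xml_find_all(doc, paste0("//", .ln(cat), "/", .ln(rec)))
  if (length(nodes) == 0) {
    return(NULL)
  }
  get <- function(node, tag) {
    xml2::xml_text(xml2::xml_find_first(node, .ln(tag)))
  }
  out <- lapply(nodes, function(s) {
    if (helix_only) {
      ty <- get(s, "conf_type_id")
      if (!is.na(ty) && !grepl("^HELX", ty)) {
        return(NULL)
      }
    }
    data.frame(
      chain = get(s, "beg_auth_asym_id"),
      start = as.integer(get(s, "beg_auth_seq_id")),
      end = as.integer(get(s, "end_auth_seq_id")),
      class = class, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Read an atomic model (PDB, PDBML or mmCIF)
#'
#' Parses all polymer residues with their atom coordinates and captures author
#' helix/sheet annotations (HELIX/SHEET records, or the struct_conf /
#' struct_sheet_range categories) when present. Alternate locations are
#' resolved to the highest-occupancy conformer (ties to the first one in the
#' file). The format is chosen by file extension (`.pdb`/`.ent`, `.xml`,
#' `.cif`).
#'
#' @param path path to the model file.
#' @return A [StructuralModel-class].
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pdb = ,
    ent = .read_model_pdb(path),
    xml = .read_model_pdbml(path),
    cif = .read_model_cif(path),
    stop("unrecognized model format: .", ext, " (expected pdb/ent, xml, cif)")
  )
}

#' @describeIn readModel atom table accessor
#' @param model a [StructuralModel-class]
#' @export
modelAtoms <- function(model) model@atoms

#' @describeIn readModel author secondary-structure ranges accessor
#' @export
authorSS <- function(model) model@authorSS

#' Per-residue table of a StructuralModel
#'
#' One row per residue in model order, with a stable residue key used by all
#' per-residue operations.
#'
#' @param model a [StructuralModel-class].
#' @return data.frame with columns `key`, `chain`, `resno`, `insert`,
#'   `resid`, `kind`.
#' @export
residueTable <- function(model) {
  at <- model@atoms
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  first <- !duplicated(key)
  data.frame(
    key = key[first], chain = at$chain[first], resno = at$resno[first],
    insert = at$insert[first], resid = at$resid[first],
    kind = at$kind[first], stringsAsFactors = FALSE
  )
}

# named coordinate lookup for one residue: matrix with rownames = atom names
.residue_coords <- function(at, rows) {
  m <- as.matrix(at[rows, c("x", "y", "z")])
  rownames(m) <- at$elety[rows]
  m
}

# split atom-row indices by residue key, in model order
.residue_index <- function(model) {
  at <- model@atoms
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  split(seq_len(nrow(at)), factor(key, levels = unique(key)))
}

#' @export
setMethod("show", "StructuralModel", function(object) {
  rt <- residueTable(object)
  cat(sprintf(
    "StructuralModel: %d atoms, %d residues (%d amino, %d nucleotide) in %d chain(s)\n",
    nrow(object@atoms), nrow(rt), sum(rt$kind == "amino"),
    sum(rt$kind == "nucleotide"), length(unique(rt$chain))
  ))
  if (nrow(object@authorSS) > 0) {
    cat(sprintf(
      "  author annotations: %d helix, %d sheet range(s)\n",
      sum(object@authorSS$class == "helix"),
      sum(object@authorSS$class == "sheet")
    ))
  }
})

#' Write a minimal PDB file for a StructuralModel
#'
#' Intended for synthetic fixtures and round-tripping; writes ATOM records
#' plus any author HELIX/SHEET ranges.
#'
#' @param model a [StructuralModel-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeModelPDB <- function(model, path) {
  at <- model@atoms
  con <- file(path, "wt")
  on.exit(close(con))
  ss <- model@authorSS
  if (nrow(ss) > 0) {
    for (i in seq_len(nrow(ss))) {
      if (ss$class[i] == "helix") {
        writeLines(sprintf(
          "HELIX  %3d %3s GLY %s %4d  GLY %s %4d  1 %31d",
          i, sprintf("H%02d", i), ss$chain[i], ss$start[i], ss$chain[i],
          ss$end[i], ss$end[i] - ss$start[i] + 1
        ), con)
      } else {
        writeLines(sprintf(
          "SHEET  %3d %3s 1 GLY %s%4d  GLY %s%4d  0",
          i, sprintf("S%02d", i), ss$chain[i], ss$start[i], ss$chain[i],
          ss$end[i]
        ), con)
      }
    }
  }
  el <- function(name) {
    e <- sub("^[0-9']*", "", name)
    substr(e, 1, 1)
  }
  for (i in seq_len(nrow(at))) {
    nm <- at$elety[i]
    nmf <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
    writeLines(sprintf(
      "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000, nmf, at$resid[i], at$chain[i], at$resno[i],
      ifelse(nzchar(at$insert[i]), at$insert[i], " "),
      at$x[i], at$y[i], at$z[i], 1.0, 0.0, el(at$elety[i])
    ), con)
  }
  writeLines("END", con)
  invisible(path)
}
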