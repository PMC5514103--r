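#' Parse a PDB or mmCIF coordinate file
#'
#' Reads a macromolecular coordinate file into a [structure_model()].
#' Hydrogens (and deuteriums) are dropped; waters are retained with role
#' "water". Alternate locations are resolved by keeping, per atom, the
#' conformer with the highest occupancy (ties broken by altloc letter
#' order). For multi-model files the first model is used unless `model`
#' says otherwise.
#'
#' @param source path to a PDB or mmCIF file
#' @param format "pdb", "cif" or "auto" (by file extension)
#' @param model 1-based model number for multi-model files
#' @param role_spec optional named character vector chain -> role passed to
#'   [assign_roles()]
#' @return structure_model
#' @export
read_structure <- function(source, format = c("auto", "pdb", "cif"),
                           model = 1L, role_spec = NULL) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("file not found: ", source)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", source)))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  multi <- model > 1L
  pdb <- tryCatch(
    if (format == "cif")
      withCallingHandlers(
        bio3d::read.cif(source, multi = multi, rm.alt = FALSE,
                        verbose = FALSE),
        warning = function(w) {
          if (grepl("beta version|helix/sheet", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    else
      bio3d::read.pdb(source, multi = multi, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("parse error in '", source, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("empty coordinate set in '", source, "'")
  if (multi) {
    nmod <- nrow(pdb$xyz)
    if (model > nmod) stop("model ", model, " requested but file has ", nmod)
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- toupper(trimws(elem))
  guess <- guess_element(at$elety)
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]
  at2 <- data.frame(
    serial = at$eleno, atom = at$elety, resname = toupper(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    b = ifelse(is.na(at$b), 0, at$b),
    element = elem, type = at$type, stringsAsFactors = FALSE)
  ## common water names to HOH
  at2$resname[at2$resname %in% c("WAT", "H2O", "DOD")] <- "HOH"
  at2 <- at2[!(at2$element %in% c("H", "D")), , drop = FALSE]
  at2 <- resolve_altloc(at2)
  if (nrow(at2) == 0) stop("empty coordinate set in '", source, "'")
  rownames(at2) <- NULL
  structure_model(at2, source_id = basename(source), role_map = role_spec)
}

## element from PDB atom name: strip digits/primes, handle leading digit
guess_element <- function(elety) {
  nm <- gsub("[0-9'\"*]", "", trimws(elety))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA") &
           nchar(trimws(elety)) > 3, two, one)
}

## keep, per (residue, atom name), the highest-occupancy altloc;
## ties broken by altloc letter order; blank altloc always kept
resolve_altloc <- function(at) {
  has_alt <- at$alt != ""
  if (!any(has_alt)) return(at)
  key <- paste(residue_uid(at), at$atom, sep = "|")
  ord <- order(key, -at$occ, at$alt)
  at_o <- at[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- at_o[keep, , drop = FALSE]
  out[order(out$serial), , drop = FALSE]
}

#' Write a model as PDB-format text
#'
#' Fixed-column PDB output that round-trips through [read_structure()].
#' Water residues are written as HETATM records with resname HOH.
#'
#' @param model structure_model
#' @param file optional path; when NULL the text is returned invisibly only
#' @return character vector of PDB lines (invisibly when `file` given)
#' @export
write_pdb_model <- function(model, file = NULL) {
  at <- model$atoms
  if (nrow(at) == 0) stop("cannot write an empty model")
  if (any(nchar(at$chain) > 1))
    stop("PDB format requires 1-character chain ids; offending: ",
         paste(unique(at$chain[nchar(at$chain) > 1]), collapse = ", "))
  type <- ifelse(at$resname == "HOH", "HETATM",
                 ifelse(at$type %in% c("ATOM", "HETATM"), at$type, "ATOM"))
  ## PDB atom-name column convention: names of <4 chars whose element symbol
  ## is 1 char start in column 14
  nm <- at$atom
  pad <- nchar(nm) < 4 & nchar(at$element) == 1
  nm[pad] <- sprintf(" %-3s", nm[pad])
  nm[!pad] <- sprintf("%-4s", nm[!pad])
  lines <- sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   type, at$serial %% 100000L, nm, " ",
                   substr(at$resname, 1, 3), at$chain, at$resno,
                   ifelse(at$icode == "", " ", at$icode),
                   at$x, at$y, at$z, at$occ, at$b, at$element)
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
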