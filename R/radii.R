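#' Load a van der Waals radii table
#'
#' Radii tables are plain TSV config files mapping (res_name, atom_name) to
#' a radius in Angstrom, with `*` rows for residue-independent atom names
#' and `ELEMENT` rows as element-level fallback. The packaged default is a
#' Chothia-style set (trigonal C 1.76, tetrahedral C 1.87, N 1.65, O 1.40,
#' S 1.85) with probe radius 1.4 A used throughout the package.
#'
#' @param file path to a radii TSV; default is the packaged table
#' @param name identifier recorded in SASA results
#' @return object of class `radii_table`
#' @export
load_radii_table <- function(file = NULL, name = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "vdw_radii.tsv", package = "abitope")
    name <- name %||% "chothia76"
  }
  name <- name %||% tools::file_path_sans_ext(basename(file))
  tab <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("res_name", "atom_name", "radius_A") %in% names(tab)))
    stop("radii table must have columns res_name, atom_name, radius_A")
  if (any(tab$radius_A < 0.5 | tab$radius_A > 3.0))
    stop("radii outside the plausible [0.5, 3.0] A range")
  elem <- tab[tab$res_name == "ELEMENT", , drop = FALSE]
  need <- c("C", "N", "O", "S")
  if (!all(need %in% elem$atom_name))
    stop("element fallback must cover C, N, O, S")
  out <- list(
    specific = tab[tab$res_name != "ELEMENT", , drop = FALSE],
    element = stats::setNames(elem$radius_A, elem$atom_name),
    name = name)
  class(out) <- "radii_table"
  out
}

#' @export
print.radii_table <- function(x, ...) {
  cat(sprintf("radii_table '%s': %d specific rules, %d element fallbacks\n",
              x$name, nrow(x$specific), length(x$element)))
  invisible(x)
}

#' Assign van der Waals radii to every heavy atom
#'
#' Lookup order: exact (res_name, atom_name) rule, then residue-independent
#' (`*`, atom_name) rule, then element fallback. Waters get the O radius.
#' Idempotent; errors if any atom's element has no fallback.
#'
#' @param model structure_model
#' @param table radii_table from [load_radii_table()]
#' @return model with a `radius` column and `radii_name` attribute set
#' @export
assign_radii <- function(model, table = load_radii_table()) {
  at <- model$atoms
  r <- rep(NA_real_, nrow(at))
  sp <- table$specific
  exact <- sp[sp$res_name != "*", , drop = FALSE]
  star <- sp[sp$res_name == "*", , drop = FALSE]
  i <- match(paste(at$resname, at$atom), paste(exact$res_name, exact$atom_name))
  r[!is.na(i)] <- exact$radius_A[i[!is.na(i)]]
  j <- match(at$atom, star$atom_name)
  fill <- is.na(r) & !is.na(j)
  r[fill] <- star$radius_A[j[fill]]
  k <- match(at$element, names(table$element))
  fill <- is.na(r) & !is.na(k)
  r[fill] <- table$element[k[fill]]
  if (anyNA(r)) {
    bad <- unique(paste0(at$resname, "/", at$atom, " (element ",
                         at$element, ")")[is.na(r)])
    stop("no radius rule for: ", paste(utils::head(bad, 10), collapse = ", "))
  }
  model$atoms$radius <- r
  model$radii_name <- table$name
  model
}
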