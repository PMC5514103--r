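#' @title End-to-end interface report and command-line interface
#' @description Orchestrates the full analysis from a structured config:
#'   per-complex buried area and contact tables, cross-complex epitope
#'   overlap, loop-deviation and elbow tables, homolog cross-reactivity
#'   and glycosylation sections. Accession ids resolve only against a
#'   local cache directory; the package never downloads.
#' @name cli_report
NULL

#' Rename chains of a model
#' @param model structure_model
#' @param map named character vector new_id -> old_id
#' @return model containing exactly the mapped chains, renamed
#' @export
rename_chains <- function(model, map) {
  sub <- select_atoms(model, chain = unname(map))
  new <- names(map)[match(sub$atoms$chain, unname(map))]
  sub$atoms$chain <- new
  rm <- sub$role_map
  names_new <- names(map)[match(names(rm), unname(map))]
  names(rm) <- names_new
  sub$role_map <- rm
  sub
}

#' Resolve a structure input (path or accession) against a local cache
#'
#' A path is returned as-is. A 4-character accession id is looked up as
#' `<cache_dir>/<id>.pdb` or `.cif`. Nothing is ever downloaded: absent
#' cache entries are an error telling the user what to fetch.
#'
#' @param x file path or accession id
#' @param cache_dir local cache directory (default: option
#'   `abitope.cache`, falling back to `~/.cache/abitope`)
#' @return existing file path
#' @export
resolve_input <- function(x, cache_dir = getOption("abitope.cache",
                                                   "~/.cache/abitope")) {
  if (file.exists(x)) return(x)
  if (grepl("^[0-9][A-Za-z0-9]{3}$", x)) {
    for (ext in c("pdb", "cif")) {
      p <- file.path(path.expand(cache_dir), paste0(tolower(x), ".", ext))
      if (file.exists(p)) return(p)
      p <- file.path(path.expand(cache_dir), paste0(toupper(x), ".", ext))
      if (file.exists(p)) return(p)
    }
    stop("accession '", x, "' not found in cache dir '", cache_dir,
         "'; download the coordinate file there manually (this tool ",
         "never fetches from the network)")
  }
  stop("input not found: ", x)
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

config_criteria <- function(config) {
  do.call(contact_criteria, config$criteria %||% list())
}

load_input <- function(entry, criteria, cache_dir) {
  path <- resolve_input(entry$path %||% entry$id, cache_dir)
  roles <- unlist(entry$roles)
  m <- read_structure(path, format = entry$format %||% "auto",
                      role_spec = roles)
  assign_radii(m)
}

#' Run the full interface report
#'
#' @param config list or YAML path. Fields: `inputs` (list of entries with
#'   `id`, `path` (or cacheable accession), optional `format`, `roles`
#'   (chain -> role)), optional `criteria` (cutoff overrides, see
#'   [contact_criteria()]), optional `region_map` (TSV path), optional
#'   `loop_regions` (region names for the deviation table), optional
#'   `elbow` (`input`, `copies` = list of chain maps, `v_resno`,
#'   `c_resno`, `chain`), optional `crossreact` (`homolog` entry +
#'   `target` chain/resno), optional `glyco` (`positions`, optionally
#'   `sequence` + `offset`), `output_dir`.
#' @param cache_dir accession cache directory
#' @return report bundle (list); also written as JSON/TSV when
#'   `config$output_dir` is set
#' @export
run_interface_report <- function(config,
                                 cache_dir = getOption("abitope.cache",
                                                       "~/.cache/abitope")) {
  config <- load_config(config)
  criteria <- config_criteria(config)
  region_map <- if (!is.null(config$region_map))
    load_region_map(config$region_map) else tryCatch(load_region_map(),
                                                     error = function(e) NULL)
  bundle <- list(params = criteria, complexes = list(), warnings = character())
  models <- list()
  epis <- list()
  for (entry in config$inputs) {
    id <- entry$id %||% basename(entry$path)
    res <- tryCatch({
      m <- load_input(entry, criteria, cache_dir)
      models[[id]] <- m
      side_a <- list(role = "antigen")
      side_b <- list(role = c("heavy", "light"))
      summ <- buried_area(m, side_a, side_b, criteria)
      contacts <- contact_table(m, side_a, side_b, criteria)
      epi <- epitope_set(m, binder_id = id, criteria = criteria,
                         region_map = region_map)
      epis[[id]] <- epi
      list(
        id = id, source = m$source_id,
        bsa_A2 = summ$bsa_total,
        contribution_binder = as.list(chain_contribution(summ, "b")),
        n_interface_residues_antigen = length(summ$residues_a),
        n_interface_residues_binder = length(summ$residues_b),
        antigen_copies_asu = asu_copy_count(m),
        epitope = list(residues = epi$residues$label,
                       regions = sort(unique(epi$residues$region))),
        contact_counts = as.list(contacts$counts),
        n_bridging_waters = contacts$n_bridging_waters,
        contact_table = contacts$table)
    }, error = function(e) {
      list(id = id, error = conditionMessage(e))
    })
    if (!is.null(res$error))
      bundle$warnings <- c(bundle$warnings,
                           sprintf("stage interface, input %s: %s", id,
                                   res$error))
    bundle$complexes[[id]] <- res
  }
  if (length(epis) >= 2)
    bundle$epitope_overlap <- tryCatch({
      ov <- epitope_overlap(epis)
      list(shared_residues = ov$intersection$label,
           jaccard = ov$jaccard)
    }, error = function(e) {
      bundle$warnings <<- c(bundle$warnings,
                            paste("stage epitope_overlap:",
                                  conditionMessage(e)))
      NULL
    })
  if (!is.null(config$loop_regions) && length(models) >= 2) {
    ids <- names(models)
    devs <- list()
    for (rg in config$loop_regions) {
      d <- tryCatch(loop_deviation(models[[ids[1]]], models[[ids[2]]], rg,
                                   region_map),
                    error = function(e) NULL)
      if (!is.null(d))
        devs[[rg]] <- list(mean_A = d$mean, max_A = d$max,
                           core_rmsd_A = d$core_rmsd)
    }
    bundle$loop_deviation <- list(pair = ids[1:2], regions = devs)
  }
  if (!is.null(config$elbow)) {
    bundle$elbow <- tryCatch({
      m <- models[[config$elbow$input]]
      copies <- lapply(config$elbow$copies, function(cm)
        rename_chains(m, unlist(cm)))
      ch <- config$elbow$chain %||% names(config$elbow$copies[[1]])[1]
      es <- elbow_swing(copies,
                        v_sel = list(chain = ch,
                                     resno = config$elbow$v_resno),
                        c_sel = list(chain = ch,
                                     resno = config$elbow$c_resno))
      list(max_swing_deg = es$max_angle_deg, pairwise_deg = es$pairwise_deg)
    }, error = function(e) {
      bundle$warnings <<- c(bundle$warnings,
                            paste("stage elbow:", conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(config$crossreact)) {
    bundle$crossreact <- tryCatch({
      hom <- load_input(config$crossreact$homolog, criteria, cache_dir)
      cid <- config$crossreact$complex %||% names(models)[1]
      cm <- models[[cid]]
      ant <- select_atoms(cm, role = "antigen")
      al <- structural_alignment(hom, ant)
      tgt <- config$crossreact$target
      cr <- graft_clash_scan(cm, hom, al,
                             list(chain = tgt$chain, resno = tgt$resno))
      tp <- al$pairs[al$pairs$resno_a == tgt$resno, , drop = FALSE]
      list(complex = cid, aligned_pairs = nrow(al$pairs),
           alignment_rmsd_A = al$fit$rmsd,
           target_pairs_with = if (nrow(tp))
             sprintf("%s%d", aa_three_to_one(tp$resname_b[1]),
                     tp$resno_b[1]) else NA,
           clash_count = cr$count, max_overlap_A = cr$max_overlap)
    }, error = function(e) {
      bundle$warnings <<- c(bundle$warnings,
                            paste("stage crossreact:", conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(config$glyco)) {
    bundle$glyco <- tryCatch({
      out <- list()
      if (!is.null(config$glyco$sequence))
        out$sequons <- find_sequons(config$glyco$sequence,
                                    config$glyco$offset %||% 0L)
      if (!is.null(config$glyco$positions) && length(epis)) {
        cid <- config$glyco$complex %||% names(models)[1]
        out$epitope_distance <-
          glyco_epitope_distance(models[[cid]],
                                 unlist(config$glyco$positions),
                                 epis[[cid]])
      }
      out
    }, error = function(e) {
      bundle$warnings <<- c(bundle$warnings,
                            paste("stage glyco:", conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  class(bundle) <- "interface_report"
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slim <- bundle
  for (id in names(slim$complexes)) {
    tab <- slim$complexes[[id]]$contact_table
    if (!is.null(tab))
      utils::write.table(tab, file.path(dir, paste0("contacts_", id, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    slim$complexes[[id]]$contact_table <- NULL
  }
  slim$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  for (id in names(bundle$complexes)) {
    cx <- bundle$complexes[[id]]
    if (!is.null(cx$error)) {
      writeLines(sprintf("%s: ERROR %s", id, cx$error), con)
    } else {
      writeLines(sprintf(
        "%s: BSA %.0f A^2; %d antigen interface residues; contacts H-bond %d, salt %d, vdw %d; %d bridging waters",
        id, cx$bsa_A2, cx$n_interface_residues_antigen,
        cx$contact_counts$hydrogen_bond, cx$contact_counts$salt_bridge,
        cx$contact_counts$vdw, cx$n_bridging_waters), con)
    }
  }
  if (!is.null(bundle$epitope_overlap))
    writeLines(paste("shared epitope:",
                     paste(bundle$epitope_overlap$shared_residues,
                           collapse = " ")), con)
  invisible(dir)
}

#' @export
print.interface_report <- function(x, ...) {
  cat("interface_report:", length(x$complexes), "complex(es)\n")
  for (id in names(x$complexes)) {
    cx <- x$complexes[[id]]
    if (!is.null(cx$error)) cat(sprintf("  %s: ERROR %s\n", id, cx$error))
    else cat(sprintf("  %s: BSA %.0f A^2, %d epitope residues\n", id,
                     cx$bsa_A2, cx$n_interface_residues_antigen))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Infer antigen/Fab chain grouping in an antibody-complex deposition
#'
#' Heuristic for depositions whose chain ids are not known in advance:
#' protein chains with `antigen_span` residues are taken as antigen
#' copies; each antigen's Fab partners are the two larger protein chains
#' with the most heavy atoms within `contact_cutoff` of it, and of those
#' the chain with the larger contact count is labelled heavy. The heavy /
#' light call is a labelling convention for downstream reports; verify it
#' against the deposition when chain identity matters.
#'
#' @param model structure_model
#' @param antigen_span inclusive residue-count range identifying antigen
#'   chains (default c(80, 150), an IgSF V-set domain)
#' @param contact_cutoff Angstrom (default 4.5)
#' @return list of list(antigen, heavy, light) chain ids, one per antigen
#'   copy
#' @export
infer_fab_complexes <- function(model, antigen_span = c(80, 150),
                                contact_cutoff = 4.5) {
  at <- model$atoms[model$atoms$resname != "HOH", , drop = FALSE]
  nres <- tapply(paste(at$resno, at$icode), at$chain,
                 function(v) length(unique(v)))
  ants <- names(nres)[nres >= antigen_span[1] & nres <= antigen_span[2]]
  others <- setdiff(names(nres), ants)
  if (!length(ants)) stop("no antigen-sized chains found")
  xyz_of <- function(ch) as.matrix(at[at$chain == ch, c("x", "y", "z")])
  out <- list()
  for (a in ants) {
    xa <- xyz_of(a)
    ncont <- vapply(others, function(b) {
      xb <- xyz_of(b)
      np <- neighbor_pairs(rbind(xa, xb), contact_cutoff)
      sum((np$i <= nrow(xa)) != (np$j <= nrow(xa)))
    }, numeric(1))
    part <- names(sort(ncont, decreasing = TRUE))[1:2]
    part <- part[!is.na(part) & ncont[part] > 0]
    if (length(part) < 2) next
    out[[length(out) + 1]] <- list(antigen = a, heavy = part[1],
                                   light = part[2])
  }
  out
}

## ---- command-line interface ---------------------------------------------

parse_argv <- function(argv) {
  opts <- list(); pos <- character()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i == length(argv) || grepl("^--", argv[i + 1])) {
        opts[[key]] <- TRUE
      } else {
        opts[[key]] <- argv[i + 1]
        i <- i + 1
      }
    } else pos <- c(pos, a)
    i <- i + 1
  }
  list(opts = opts, pos = pos)
}

cli_usage <- function() {
  cat("usage: abitope <subcommand> [options]\n",
      "subcommands:\n",
      "  sasa      --pdb FILE [--probe R] [--n-points N]\n",
      "  interface --pdb FILE --antigen CHAINS --binder CHAINS\n",
      "  contacts  --pdb FILE --antigen CHAINS --binder CHAINS [--out FILE]\n",
      "  compare   --config FILE\n",
      "  crossreact --config FILE\n",
      "  glyco     --config FILE\n",
      "  fixtures  --kind KIND --seed N [--out DIR]\n",
      "  report    --config FILE [--out DIR]\n",
      "options: --seed N, --probe R, --cutoff-hbond D, --cutoff-salt D,\n",
      "         --cutoff-vdw D (override config)\n", sep = "")
}

cli_criteria <- function(opts) {
  contact_criteria(
    hbond = as.numeric(opts[["cutoff-hbond"]] %||% 3.5),
    salt_bridge = as.numeric(opts[["cutoff-salt"]] %||% 4.0),
    vdw = as.numeric(opts[["cutoff-vdw"]] %||% 4.0),
    probe = as.numeric(opts[["probe"]] %||% 1.4))
}

cli_load <- function(opts) {
  if (is.null(opts$pdb)) stop("--pdb is required", call. = FALSE)
  ants <- strsplit(opts$antigen %||% "", ",")[[1]]
  bind <- strsplit(opts$binder %||% "", ",")[[1]]
  roles <- c(stats::setNames(rep("antigen", length(ants)), ants),
             stats::setNames(rep("heavy", length(bind)), bind))
  m <- read_structure(opts$pdb, role_spec = if (length(roles)) roles)
  assign_radii(m)
}

#' Command-line entry point
#'
#' Thin argv-driven interface over the package functions; the installed
#' `abitope` Rscript (inst/scripts) forwards to this.
#'
#' @param argv character vector of arguments (excluding the program name)
#' @return exit code: 0 success, 1 usage error, 2 data error
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) { cli_usage(); return(1L) }
  sub <- argv[1]
  pa <- parse_argv(argv[-1])
  opts <- pa$opts
  run <- function(expr) {
    tryCatch({ expr; 0L },
             usage_error = function(e) { message(conditionMessage(e)); 1L },
             error = function(e) { message("error: ", conditionMessage(e)); 2L })
  }
  tsv <- function(df) utils::write.table(df, stdout(), sep = "\t",
                                         row.names = FALSE, quote = FALSE)
  switch(sub,
    sasa = run({
      m <- cli_load(opts)
      s <- shrake_rupley_sasa(m, probe = as.numeric(opts$probe %||% 1.4),
                              n_points = as.numeric(opts[["n-points"]] %||% 960))
      per_chain <- tapply(s$per_atom$area, s$per_atom$chain, sum)
      tsv(data.frame(chain = c(names(per_chain), "TOTAL"),
                     sasa_A2 = round(c(as.numeric(per_chain), s$total), 1)))
    }),
    interface = run({
      m <- cli_load(opts)
      cr <- cli_criteria(opts)
      bs <- buried_area(m, list(role = "antigen"), list(role = "heavy"), cr)
      contrib <- chain_contribution(bs, "b")
      tsv(data.frame(
        metric = c("bsa_A2", "n_interface_residues_antigen",
                   "n_interface_residues_binder",
                   paste0("contribution_", names(contrib))),
        value = c(round(bs$bsa_total, 1), length(bs$residues_a),
                  length(bs$residues_b), round(unname(contrib), 3))))
    }),
    contacts = run({
      m <- cli_load(opts)
      cr <- cli_criteria(opts)
      ct <- contact_table(m, list(role = "antigen"), list(role = "heavy"), cr)
      if (!is.null(opts$out))
        utils::write.table(ct$table, opts$out, sep = "\t",
                           row.names = FALSE, quote = FALSE)
      else tsv(ct$table)
    }),
    compare = ,
    crossreact = ,
    glyco = ,
    report = run({
      if (is.null(opts$config))
        stop(simpleCondition("--config is required",
                             class = c("usage_error", "condition")))
      cfg <- load_config(opts$config)
      if (!is.null(opts$out)) cfg$output_dir <- opts$out
      b <- run_interface_report(cfg)
      print(b)
    }),
    fixtures = run({
      kind <- opts$kind %||% "toy_complex"
      seed <- as.integer(opts$seed %||% 1)
      fix <- switch(kind,
        sphere_cluster = make_sphere_cluster(seed = seed),
        toy_complex = make_toy_complex(seed = seed),
        hinged_fab = make_hinged_fab(seed = seed),
        homolog_pair = make_homolog_pair(seed = seed),
        stop(simpleCondition(paste("unknown fixture kind:", kind),
                             class = c("usage_error", "condition"))))
      out <- opts$out %||% "."
      paths <- write_fixture(fix, out, paste0(kind, "_seed", seed))
      cat(paste(paths, collapse = "\n"), "\n")
    }),
    { cli_usage(); 1L }
  )
}
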