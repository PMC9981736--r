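# Single entry point wiring the modules into the four analyses (structure
# summary / graft + interface / alignment conservation + covariation / NMR
# shifts) from one JSON configuration, with machine-readable stage reports.

#' Run the analysis pipeline from a configuration
#'
#' The configuration is a JSON document (path or pre-parsed list) with one
#' block per requested stage; stages run in dependency order and each yields
#' a `RunReport` carrying its parameters and headline numbers. Recognised
#' stages:
#'
#' * `structure`: `{"file": path}` - read + summarize (+ optional
#'   `"contact_scan": {"radius": r}`).
#' * `simulate_graft` / `graft`: synthetic grafting scenario (seeded) or a
#'   user graft `{"template": path, "components": [{"file":, "anchor":
#'   {"component_range": [a,b], "component_chains": [..], "template_range":
#'   [a,b], "template_chains": [..]}}, ...]}`, followed by clash counting
#'   and inter-domain contacts.
#' * `simulate_msa` / `covariation`: synthetic alignment (seeded) or
#'   `{"alignment": path}`; MI-APC scores, and agreement vs the graft
#'   stage's contacts when available.
#' * `simulate_shifts` / `nmr`: synthetic shift pair (seeded) or
#'   `{"reference": path, "modified": path}`; CSP classes and secondary
#'   shifts.
#'
#' A top-level `"seed"` seeds every synthetic stage.
#'
#' @param config path to a JSON file, or an equivalent named list.
#' @return named list of `RunReport`s (class `RunReportSet`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("run_pipeline: no such config: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  seed <- config$seed %||% 1
  reports <- list()
  contacts <- NULL

  report <- function(stage, params, headline, outputs = list()) {
    structure(list(stage = stage, params = params, headline = headline,
                   outputs = outputs), class = "RunReport")
  }

  if (!is.null(config$structure)) {
    cfg <- config$structure
    if (is.null(cfg$file)) stop("run_pipeline: structure stage needs 'file'")
    s <- read_structure(cfg$file)
    sm <- summarize_structure(s)
    head <- list(n_protein_atoms = sm$n_protein_atoms,
                 n_water = sm$n_water, mean_b_protein = sm$mean_b_protein)
    scan <- NULL
    if (!is.null(cfg$contact_scan)) {
      scan <- crystal_contact_scan(s, radius = cfg$contact_scan$radius %||% 5,
                                   n_points = cfg$contact_scan$n_points %||% 240)
      head$max_interface_area <- if (length(scan))
        max(vapply(scan, function(e) e$report$area, 0)) else 0
    }
    reports$structure <- report("structure", cfg, head,
                                list(summary = sm, contact_scan = scan))
  }

  if (isTRUE(config$simulate_graft) || is.list(config$simulate_graft) ||
      !is.null(config$graft)) {
    if (!is.null(config$graft)) {
      cfg <- config$graft
      template <- read_structure(cfg$template)
      comps <- lapply(cfg$components, function(cc) {
        anc <- cc$anchor
        list(structure = read_structure(cc$file),
             anchor = anchor_spec(
               atom_selection(chains = anc$component_chains,
                              residue_ranges = list(unlist(anc$component_range)),
                              atom_class = "CA"),
               atom_selection(chains = anc$template_chains,
                              residue_ranges = list(unlist(anc$template_range)),
                              atom_class = "CA"),
               label = anc$label %||% ""))
      })
      params <- cfg
    } else {
      cfg <- if (is.list(config$simulate_graft)) config$simulate_graft
        else list()
      sc <- make_graft_scenario(seed = cfg$seed %||% seed,
                                noise_sd = cfg$noise_sd %||% 0)
      template <- sc$template
      comps <- list(list(structure = sc$donors$A, anchor = sc$anchors$A),
                    list(structure = sc$donors$B, anchor = sc$anchors$B))
      params <- cfg
    }
    model <- graft_complex(template, comps)
    ch <- vapply(model$provenance, function(p) p$chain[1], "")
    gA <- model$provenance[[1]]$chain
    gB <- unlist(lapply(model$provenance[-1], function(p) p$chain))
    clash <- count_interdomain_clashes(model, gA, gB)
    at <- select_atoms(model$assembly)
    contacts <- residue_contacts(at[at$chain %in% gA, ],
                                 at[at$chain %in% gB, ])
    reports$graft <- report(
      "graft", params,
      list(anchor_rmsd = vapply(model$provenance,
                                function(p) p$anchor_rmsd, 0),
           n_clashes = clash$n_clashes,
           n_contacts = nrow(contacts)),
      list(model = model, clash = clash, contacts = contacts))
  }

  if (isTRUE(config$simulate_msa) || is.list(config$simulate_msa) ||
      !is.null(config$covariation)) {
    if (!is.null(config$covariation) &&
        !is.null(config$covariation$alignment)) {
      aln <- read_alignment(config$covariation$alignment)
      params <- config$covariation
    } else {
      cfg <- if (is.list(config$simulate_msa)) config$simulate_msa else list()
      aln <- simulate_msa(seed = cfg$seed %||% seed,
                          n_seq = cfg$n_seq %||% 500,
                          n_col = cfg$n_col %||% 60)
      params <- cfg
    }
    cv <- covariation_scores(aln)
    head <- list(n_columns = length(cv$columns), n_eff = cv$n_eff,
                 n_peaks = nrow(top_couplings(cv)))
    agree <- NULL
    if (!is.null(contacts)) {
      agree <- covariation_vs_distance(cv, contacts)
      head$precision_tight <- agree$precision_tight
      head$precision_loose <- agree$precision_loose
    }
    reports$covariation <- report("covariation", params, head,
                                  list(scores = cv, agreement = agree))
  }

  if (isTRUE(config$simulate_shifts) || is.list(config$simulate_shifts) ||
      !is.null(config$nmr)) {
    if (!is.null(config$nmr) && !is.null(config$nmr$reference)) {
      ref <- read_shift_table(config$nmr$reference)
      mod <- read_shift_table(config$nmr$modified)
      params <- config$nmr
    } else {
      cfg <- if (is.list(config$simulate_shifts)) config$simulate_shifts
        else list()
      sp <- simulate_shift_pair(seed = cfg$seed %||% seed)
      ref <- sp$ref; mod <- sp$mod
      params <- cfg
    }
    prof <- csp(ref, mod)
    sec <- secondary_shifts(ref)
    reports$nmr <- report(
      "nmr", params,
      list(n_strong = sum(prof$class == "strong", na.rm = TRUE),
           n_medium = sum(prof$class == "medium", na.rm = TRUE),
           n_helix = sum(sec$propensity == "helix", na.rm = TRUE)),
      list(csp = prof, secondary = sec))
  }

  if (!length(reports))
    stop("run_pipeline: configuration requests no recognised stage")
  class(reports) <- "RunReportSet"
  reports
}

#' @export
print.RunReportSet <- function(x, ...) {
  for (r in x) {
    cat(sprintf("[%s]\n", r$stage))
    for (nm in names(r$headline)) {
      v <- r$headline[[nm]]
      cat(sprintf("  %s: %s\n", nm,
                  paste(signif(unlist(v), 4), collapse = " ")))
    }
  }
  invisible(x)
}
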