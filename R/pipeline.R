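## cli_pipeline: orchestration of the two workflows --
## design:    prepare -> graft -> design -> filter -> rank
## maturation: count -> enrich -> dual-select -> library design
## with config, quarantine of failing items, and a reproducibility manifest.

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

#' Pipeline configuration
#'
#' @param graft A [graft_config()].
#' @param design A [design_config()].
#' @param thresholds A [filter_thresholds()].
#' @param enrich_threshold,enrich_min_coverage,pseudocount Maturation
#'   enrichment settings.
#' @param diversity_cap Combinatorial library cap.
#' @param max_grafts Graft solutions carried forward per scaffold.
#' @param seed Master seed propagated to every stochastic stage.
#' @param out_dir Optional output directory (CSV/JSON artifacts written
#'   when set).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(graft = graft_config(), design = design_config(),
                            thresholds = filter_thresholds(),
                            enrich_threshold = 1.0, enrich_min_coverage = 10,
                            pseudocount = 0.5, diversity_cap = 4e7,
                            max_grafts = 1, seed = 1, out_dir = NULL) {
  design$seed <- seed
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the design workflow
#'
#' For each scaffold: scan graft windows against the motif, apply the best
#' accepted grafts, run the two-shell design protocol, compute the filter
#' report, and rank. Items failing any stage are quarantined (the pipeline
#' continues) and reported. Ranking: filter gates first, then ascending
#' predicted binding energy (a documented composite; selecting real
#' designs typically also involves human judgment).
#'
#' @param context Target structure (`bh3_structure`).
#' @param motif A `bh3_motif` from [prepare_context_motif()].
#' @param scaffolds Named list of single-chain scaffold structures.
#' @param cfg A [pipeline_config()].
#' @return List: `table` (ranked data.frame), `designs` (structures),
#'   `failures`, `manifest`.
#' @export
run_design_pipeline <- function(context, motif, scaffolds, cfg = pipeline_config()) {
  if (inherits(scaffolds, "bh3_structure")) scaffolds <- list(scaffold = scaffolds)
  if (is.null(names(scaffolds)))
    names(scaffolds) <- paste0("scaffold", seq_along(scaffolds))
  rows <- list(); designs <- list(); failures <- list()
  for (nm in names(scaffolds)) {
    res <- tryCatch({
      sc <- scaffolds[[nm]]
      sols <- find_graft_sites(motif, sc, cfg$graft, context = context)
      if (!length(sols)) stop("no accepted graft windows")
      sols <- sols[seq_len(min(cfg$max_grafts, length(sols)))]
      lapply(seq_along(sols), function(i) {
        sol <- sols[[i]]
        cx <- apply_graft(sol, motif, sc, context, binder_chain = "X")
        hot <- sol$window_resnos[motif$hotspot_indices]
        des <- design_protocol(cx, cfg$design, binder_chain = "X", hotspots = hot)
        rep <- filter_report(des$complex, cfg$thresholds, split = "X")
        list(id = sprintf("%s_g%02d", nm, i), sol = sol, design = des, report = rep)
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[nm]] <- conditionMessage(res)
      next
    }
    for (r in res) {
      designs[[r$id]] <- r$design$complex
      rows[[r$id]] <- data.frame(
        id = r$id, scaffold = nm, window = r$sol$window_start,
        full_bb_rmsd = r$sol$full_bb_rmsd, endpoint_rmsd = r$sol$endpoint_rmsd,
        clash = r$sol$clash_score,
        binding_energy = r$report$binding_energy, sc = r$report$sc,
        buried_unsat = r$report$buried_unsat,
        omega_failures = r$report$omega_failures,
        pass = r$report$pass_all, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), pass = logical(), binding_energy = numeric())
  if (nrow(tab)) {
    tab <- tab[order(-tab$pass, tab$binding_energy), , drop = FALSE]
    rownames(tab) <- NULL
  }
  manifest <- list(
    stage_params = list(graft = unclass(cfg$graft), design = unclass(cfg$design),
                        thresholds = unclass(cfg$thresholds)),
    seed = cfg$seed,
    inputs = list(context = md5_of(context), motif = md5_of(motif),
                  scaffolds = vapply(scaffolds, md5_of, "")),
    outputs = list(table = md5_of(tab)),
    n_failures = length(failures),
    timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(cfg$out_dir, "ranked_designs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest[setdiff(names(manifest), "timestamp")],
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    for (id in names(designs))
      write_structure(designs[[id]], file.path(cfg$out_dir, paste0(id, ".pdb")))
  }
  list(table = tab, designs = designs, failures = failures, manifest = manifest)
}

#' Run the maturation workflow
#'
#' Enrichment under the affinity and specificity sorts, dual
#' independent-enrichment selection, and degenerate-codon combinatorial
#' library construction under the diversity cap.
#'
#' @param naive,affinity,specificity `pool_counts` objects (all three
#'   required; a missing condition is an error naming it).
#' @param cfg A [pipeline_config()].
#' @return List: `enrichment` (aff/spec results), `selected`, `library`,
#'   `manifest`.
#' @export
run_maturation_pipeline <- function(naive, affinity, specificity,
                                    cfg = pipeline_config()) {
  for (nm in c("naive", "affinity", "specificity")) {
    obj <- get(nm)
    if (!inherits(obj, "pool_counts"))
      stop("missing or invalid pool for condition: ", nm)
  }
  e_aff <- enrichment(naive, affinity, cfg$pseudocount,
                      cfg$enrich_threshold, cfg$enrich_min_coverage)
  e_spec <- enrichment(naive, specificity, cfg$pseudocount,
                       cfg$enrich_threshold, cfg$enrich_min_coverage)
  sel <- dual_select(e_aff, e_spec)
  lib <- design_combinatorial_library(naive$parent, sel, cap = cfg$diversity_cap)
  manifest <- list(
    params = list(pseudocount = cfg$pseudocount,
                  enrich_threshold = cfg$enrich_threshold,
                  min_coverage = cfg$enrich_min_coverage,
                  diversity_cap = cfg$diversity_cap),
    inputs = list(naive = md5_of(naive$counts), affinity = md5_of(affinity$counts),
                  specificity = md5_of(specificity$counts)),
    outputs = list(selected = md5_of(sel),
                   library = md5_of(lib[c("positions", "protein_diversity")])),
    timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(e_aff$table, file.path(cfg$out_dir, "enrichment_affinity.csv"),
                     row.names = FALSE)
    utils::write.csv(e_spec$table, file.path(cfg$out_dir, "enrichment_specificity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(parent = lib$parent,
           positions = lapply(lib$positions, function(p)
             p[c("position", "parent", "codon", "aas")]),
           protein_diversity = lib$protein_diversity,
           dna_diversity = lib$dna_diversity),
      file.path(cfg$out_dir, "library.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  list(enrichment = list(affinity = e_aff, specificity = e_spec),
       selected = sel, library = lib, manifest = manifest)
}

#' Read a variant count table from CSV
#'
#' Expected columns: `position`, `from`, `to`, `count`; optional `pool`
#' and `condition` columns select/annotate one pool.
#'
#' @param path CSV path.
#' @param pool_id Pool to extract when a `pool` column is present.
#' @param condition Condition label for the result.
#' @param parent Parent sequence (optional).
#' @param wt_count Wild-type read count.
#' @return A [pool_counts()].
#' @export
read_pool_counts <- function(path, pool_id = NULL, condition = "naive",
                             parent = NULL, wt_count = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "from", "to", "count")
  if (!all(need %in% names(df))) stop("count table must have columns: ",
                                      paste(need, collapse = ","))
  if (!is.null(pool_id) && "pool" %in% names(df))
    df <- df[df$pool == pool_id, , drop = FALSE]
  pool_counts(df[, need], wt_count = wt_count,
              pool_id = pool_id %||% "pool", condition = condition,
              parent = if (is.null(parent)) NULL else as_sequence_string(parent))
}
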