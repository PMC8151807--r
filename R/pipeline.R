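# Configuration-driven orchestration of the full analysis:
# simulate -> edit -> single-sex REML -> scale -> combined evaluation ->
# trends -> GWAS -> GREML, with a JSON run manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()];
#' supply overrides as a (possibly nested) list or a YAML file.  Stage
#' toggles live under `$stages`; simulator settings under `$sim` (passed to
#' [sim_config()]) and `$geno` ([geno_sim_config()]); the remaining entries
#' are stage parameters with the defaults of the underlying functions.
#'
#' @param overrides list (or path to a YAML file) of settings to merge over
#'   the defaults.
#' @return Configuration list.
#' @export
pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    out_dir = "calfgrow-run",
    seed = 1L,
    stages = list(simulate = TRUE, edit = TRUE, reml = TRUE,
                  evaluate = TRUE, trends = TRUE, gwas = TRUE),
    sim = list(),
    geno = list(n_snps = 500L, n_causal = 5L, causal_r2 = 0.02),
    edit = list(cap = TRUE),
    reml = list(algorithm = "AI", tol = 1e-6, max_iter = 200L),
    evaluate = list(base_year = NULL, group_rule = "dataset2"),
    trends = list(from = "1992-01-01", min_reliability = 0.9),
    gwas = list(n_perm = 2000L, min_call = 0.9, min_rel = 0.5,
                born_from = 1900L))
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  modifyList(cfg, overrides %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on one simulated data
#' set, writing every product as CSV under `cfg$out_dir` together with a
#' JSON manifest (stage timings, file list, configuration hash).  Stage
#' failures abort the run; downstream stages are not attempted.  With a
#' fixed seed the whole run is deterministic.
#'
#' @param cfg configuration from [pipeline_config()] (list or YAML path).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg) || is.null(cfg$stages)) cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_file)),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- force(expr)
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[3] - t0, 2))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[3] - t0))
    res
  }
  out <- function(f) file.path(cfg$out_dir, f)

  scfg <- do.call(sim_config, modifyList(list(seed = cfg$seed), cfg$sim))
  ped <- truth <- records <- NULL
  if (cfg$stages$simulate) {
    t_stage("simulate", {
      ped <- simulate_pedigree(scfg)
      truth <- simulate_true_values(ped, scfg)
      records <- simulate_weight_records(ped, truth, scfg)
      write_pedigree(ped, out("pedigree.csv"))
      write_records(records, out("weights.csv"))
      write.csv(truth$animals, out("truth_animals.csv"), row.names = FALSE)
      write.csv(truth$hys, out("truth_hys.csv"), row.names = FALSE)
    })
  } else {
    ped <- read_pedigree(out("pedigree.csv"))
    records <- read_records(out("weights.csv"))
  }

  edited <- NULL
  if (cfg$stages$edit) {
    edited <- t_stage("edit", {
      ed <- apply_edits(records, ped, cap = cfg$edit$cap)
      write_records(ed$records, out("yg_records.csv"))
      write.csv(ed$audit, out("edit_audit.csv"), row.names = FALSE)
      ed$records
    })
  } else if (file.exists(out("yg_records.csv"))) {
    edited <- read_records(out("yg_records.csv"))
  }

  vc_m <- vc_f <- NULL
  if (cfg$stages$reml) {
    t_stage("reml", {
      for (sx in c("M", "F")) {
        rs <- edited[edited$sex == sx, , drop = FALSE]
        fit <- reml_estimate(rs, ped, algorithm = cfg$reml$algorithm,
                             tol = cfg$reml$tol, max_iter = cfg$reml$max_iter,
                             label = c(M = "male", F = "female")[sx])
        if (sx == "M") vc_m <- fit else vc_f <- fit
      }
      vcdf <- data.frame(
        analysis = c("male", "female"),
        sigma2_a = c(vc_m$sigma2_a, vc_f$sigma2_a),
        sigma2_p = c(vc_m$sigma2_p, vc_f$sigma2_p),
        sigma2_e = c(vc_m$sigma2_e, vc_f$sigma2_e),
        se_a = c(vc_m$se["a"], vc_f$se["a"]),
        se_p = c(vc_m$se["p"], vc_f$se["p"]),
        se_e = c(vc_m$se["e"], vc_f$se["e"]),
        heritability = c(heritability(vc_m), heritability(vc_f)),
        repeatability = c(repeatability(vc_m), repeatability(vc_f)))
      write.csv(vcdf, out("variance_components.csv"), row.names = FALSE)
    })
  } else if (file.exists(out("variance_components.csv"))) {
    vcdf <- read.csv(out("variance_components.csv"))
    vc_m <- new_vc(vcdf$sigma2_a[1], vcdf$sigma2_p[1], vcdf$sigma2_e[1], label = "male")
    vc_f <- new_vc(vcdf$sigma2_a[2], vcdf$sigma2_p[2], vcdf$sigma2_e[2], label = "female")
  }

  sol <- NULL
  if (cfg$stages$evaluate) {
    sol <- t_stage("evaluate", {
      groups <- assign_groups(ped, cfg$evaluate$group_rule)
      s <- genetic_evaluation(edited, ped, vc_m, vc_f, groups = groups,
                              base_year = cfg$evaluate$base_year)
      write.csv(s$ebv, out("evaluations.csv"), row.names = FALSE)
      s
    })
  }

  if (cfg$stages$trends && !is.null(sol)) {
    t_stage("trends", {
      gt <- genetic_trend(sol$ebv$ebv, sol$ebv$birth_date, from = cfg$trends$from)
      pt <- phenotypic_trend(edited, from = cfg$trends$from)
      write.csv(data.frame(trend = c("genetic", "phenotypic"),
                           slope_kg_per_year = c(gt$slope, pt$slope),
                           se = c(gt$se, pt$se), n = c(gt$n, pt$n)),
                out("trends.csv"), row.names = FALSE)
    })
  }

  if (cfg$stages$gwas && !is.null(sol)) {
    t_stage("gwas", {
      bulls <- sol$ebv[sol$ebv$sex == "M", ]
      cohort <- select_cohort(bulls, genotyped = bulls$animal,
                              min_rel = cfg$gwas$min_rel,
                              born_from = cfg$gwas$born_from)
      if (length(cohort) < 20) {
        message("[gwas] cohort too small after filters (", length(cohort),
                "); relaxing reliability filter")
        cohort <- bulls$animal
      }
      ta <- bulls$ta[match(cohort, bulls$animal)]
      gcfg <- do.call(geno_sim_config,
                      modifyList(list(n_bulls = length(cohort), seed = cfg$seed),
                                 cfg$geno))
      g <- simulate_genotypes(gcfg, ta)
      rownames(g$dosage) <- cohort
      write_plink(g, out("genotypes"))
      g <- marker_qc(g, min_call = cfg$gwas$min_call)
      as_tab <- assoc(g$ta, g$dosage)
      pm <- max_t_permutation(g$ta, g, n_perm = cfg$gwas$n_perm,
                              seed = cfg$seed + 7L)
      res <- merge(cbind(as_tab, g$map[match(as_tab$snp, g$map$snp),
                                       c("chr", "bp")]),
                   pm[, c("snp", "p_bonferroni", "p_genomewide")], by = "snp")
      res <- res[order(res$chr, res$bp), ]
      write.csv(res, out("gwas_results.csv"), row.names = FALSE)
      grm <- build_grm(g)
      gfit <- greml(g$ta, grm)
      write.csv(data.frame(quantity = c("snp_fraction", "se"),
                           value = c(gfit$fraction, gfit$se)),
                out("greml.csv"), row.names = FALSE)
    })
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest$files <- list.files(cfg$out_dir)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
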