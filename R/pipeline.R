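# Study orchestration: per-locus summaries, divergence, windows, LD/Rm, MK,
# ML-HKA, mismatch and the three-model demographic comparison, driven by one
# declarative config with no hidden analysis constants.

#' Build / validate a run configuration
#'
#' @param loci data.frame with columns `name`, `path` (FASTA), `offset`
#'   (0-based frame offset) and `c` (inheritance scalar; 0.25 for mtDNA).
#' @param species character(2), the two group labels expected in the
#'   metadata (default `c("Euc", "Eus")`).
#' @param outdir output directory.
#' @param alpha significance level.
#' @param window_small,step_small,window_large,step_large sliding-window
#'   settings (defaults 50/10 and 100/50 bp).
#' @param theta_max theta search bound for the demographic models.
#' @param mc_samples Monte-Carlo genealogies per grid point.
#' @param seed integer seed recorded in every output.
#' @param label_schema label regex passed to [read_alignment()].
#' @return validated list of class `run_config`.
#' @export
run_config <- function(loci, species = c("Euc", "Eus"), outdir = "poldiv_out",
                       alpha = 0.05, window_small = 50L, step_small = 10L,
                       window_large = 100L, step_large = 50L,
                       theta_max = 30, mc_samples = 2000, seed = 1,
                       label_schema = default_label_schema) {
  stopifnot(is.data.frame(loci),
            all(c("name", "path", "offset", "c") %in% names(loci)))
  missing <- !file.exists(loci$path)
  if (any(missing)) {
    stop("missing input file(s): ", paste(loci$path[missing], collapse = ", "))
  }
  structure(list(loci = loci, species = species, outdir = outdir, alpha = alpha,
                 window_small = window_small, step_small = step_small,
                 window_large = window_large, step_large = step_large,
                 theta_max = theta_max, mc_samples = mc_samples, seed = seed,
                 label_schema = label_schema), class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file whose fields mirror [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$loci <- as.data.frame(j$loci, stringsAsFactors = FALSE)
  do.call(run_config, j)
}

write_tsv_report <- function(df, path, cfg, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# poldiv %s | stage: %s", as.character(utils::packageVersion("poldiv")), stage),
    sprintf("# seed: %d | alpha: %g", cfg$seed, cfg$alpha),
    sprintf("# inputs: %s", paste(sprintf("%s=%s", cfg$loci$name,
                                          unname(tools::md5sum(cfg$loci$path))),
                                  collapse = " "))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full study workflow
#'
#' Executes every stage on the configured loci and writes the report bundle
#' (TSV/JSON with provenance headers) to `cfg$outdir`. A failing stage is
#' recorded and the remaining stages still run.
#'
#' @param cfg a [run_config()].
#' @param stages character vector of stages to run (default all).
#' @return list with `status` (named "ok"/"failed: ..." per stage) and
#'   `results` (in-memory stage outputs). Attribute `exit_code` is 0 on full
#'   success, 3 if any stage failed.
#' @export
run_study <- function(cfg, stages = c("summarize", "divergence", "windows",
                                      "ld", "mk", "mlhka", "mismatch",
                                      "demography")) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  alns <- lapply(seq_len(nrow(cfg$loci)), function(i) {
    read_alignment(cfg$loci$path[i], cfg$label_schema,
                   offset = cfg$loci$offset[i])
  })
  names(alns) <- cfg$loci$name
  by_sp <- lapply(alns, split_species)
  status <- character(0)
  results <- list()
  run_stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e) e)
    if (inherits(r, "error")) {
      status[[name]] <<- paste0("failed: ", conditionMessage(r))
    } else {
      status[[name]] <<- "ok"
      results[[name]] <<- r
    }
  }

  if ("summarize" %in% stages) run_stage("summarize", {
    rows <- list()
    for (l in names(alns)) for (sp in names(by_sp[[l]])) {
      rows[[paste(l, sp)]] <- locus_summary(by_sp[[l]][[sp]], l, sp)
    }
    tab <- do.call(rbind, rows)
    write_tsv_report(tab, file.path(cfg$outdir, "locus_summary.tsv"), cfg, "summarize")
    tab
  })

  if ("divergence" %in% stages) run_stage("divergence", {
    rows <- lapply(names(alns), function(l) {
      g <- by_sp[[l]]
      d <- jc_divergence(g[[1]], g[[2]])
      data.frame(locus = l, K_raw = d$K_raw, K_JC = d$K_JC, Da = d$Da,
                 n_fixed = nrow(d$fixed_differences),
                 n_fixed_nonsyn = sum(d$fixed_differences$class == "nonsynonymous",
                                      na.rm = TRUE))
    })
    tab <- do.call(rbind, rows)
    write_tsv_report(tab, file.path(cfg$outdir, "divergence.tsv"), cfg, "divergence")
    tab
  })

  if ("windows" %in% stages) run_stage("windows", {
    out <- list()
    for (l in names(alns)) {
      g <- by_sp[[l]]
      prof <- rbind(
        cbind(statistic = "pi_pooled",
              sliding_window(alns[[l]], "pi", cfg$window_small, cfg$step_small)),
        cbind(statistic = "K",
              sliding_window(list(g[[1]], g[[2]]), "K",
                             cfg$window_large, cfg$step_large)),
        cbind(statistic = "Ka/Ks",
              sliding_window(list(g[[1]], g[[2]]), "Ka/Ks",
                             cfg$window_small, cfg$step_small)))
      prof$locus <- l
      out[[l]] <- prof
    }
    tab <- do.call(rbind, out)
    write_tsv_report(tab, file.path(cfg$outdir, "windows.tsv"), cfg, "windows")
    tab
  })

  if ("ld" %in% stages) run_stage("ld", {
    rows <- list()
    for (l in names(alns)) for (sp in names(by_sp[[l]])) {
      for (conv in c(FALSE, TRUE)) {
        r <- suppressWarnings(pairwise_ld(by_sp[[l]][[sp]], cfg$alpha,
                                          exclude_singletons = conv))
        rm_ <- hudson_kaplan_rm(by_sp[[l]][[sp]])
        rows[[paste(l, sp, conv)]] <- data.frame(
          locus = l, group = sp, exclude_singletons = conv, ZnS = r$ZnS,
          n_pairs = r$n_pairs, n_sig_raw = r$n_sig_raw,
          n_sig_bonferroni = r$n_sig_bonferroni, Rm = rm_$Rm)
      }
    }
    tab <- do.call(rbind, rows)
    write_tsv_report(tab, file.path(cfg$outdir, "ld.tsv"), cfg, "ld")
    tab
  })

  if ("mk" %in% stages) run_stage("mk", {
    rows <- list()
    for (l in names(alns)) {
      g <- by_sp[[l]]
      for (mode in c(cfg$species, "pooled")) {
        src <- if (mode == "pooled") g else g[[mode]]
        mk <- tryCatch(mk_test(src, g), error = function(e) NULL)
        if (is.null(mk)) next
        rows[[paste(l, mode)]] <- data.frame(
          locus = l, polymorphism = mode, Pn = mk$Pn, Ps = mk$Ps,
          Dn = mk$Dn, Ds = mk$Ds, p = mk$p, p_doubled = mk$p_doubled,
          NI = mk$NI)
      }
    }
    tab <- do.call(rbind, rows)
    write_tsv_report(tab, file.path(cfg$outdir, "mk.tsv"), cfg, "mk")
    tab
  })

  if ("mlhka" %in% stages) run_stage("mlhka", {
    out <- list()
    for (sp in cfg$species) {
      other <- setdiff(cfg$species, sp)
      loci_dat <- lapply(names(alns), function(l) {
        list(poly = by_sp[[l]][[sp]],
             div = list(by_sp[[l]][[sp]], by_sp[[l]][[other]]))
      })
      names(loci_dat) <- names(alns)
      dat <- hka_data(loci_dat, c_i = cfg$loci$c)
      null <- fit_mlhka(dat, character(0), seed = cfg$seed)
      fits <- lapply(names(alns), function(l) fit_mlhka(dat, l, seed = cfg$seed))
      rows <- do.call(rbind, lapply(seq_along(fits), function(i) {
        lr <- lrt(null, fits[[i]])
        data.frame(species = sp, free_locus = names(alns)[i],
                   k = fits[[i]]$k[[names(alns)[i]]], lnL = fits[[i]]$lnL,
                   lnL_null = null$lnL, LRT = lr$statistic, p = lr$p)
      }))
      out[[sp]] <- rows
    }
    tab <- do.call(rbind, out)
    write_tsv_report(tab, file.path(cfg$outdir, "mlhka.tsv"), cfg, "mlhka")
    tab
  })

  if ("mismatch" %in% stages) run_stage("mismatch", {
    rows <- list()
    for (l in names(alns)) for (sp in names(by_sp[[l]])) {
      a <- by_sp[[l]][[sp]]
      ft <- fit_expansion(aln = a)
      rows[[paste(l, sp)]] <- data.frame(
        locus = l, group = sp, tau = ft$tau, theta0 = ft$theta0,
        theta1 = ft$theta1, sse_expansion = ft$sse_expansion,
        sse_constant = ft$sse_constant, R2 = ft$R2,
        raggedness = ft$raggedness)
      spec_path <- file.path(cfg$outdir, sprintf("mismatch_%s_%s.tsv", l, sp))
      spec_tab <- data.frame(diffs = as.integer(names(ft$observed)),
                             observed = as.numeric(ft$observed),
                             expected_constant = as.numeric(ft$expected_constant),
                             expected_expansion = as.numeric(ft$expected_expansion))
      write_tsv_report(spec_tab, spec_path, cfg, "mismatch")
    }
    tab <- do.call(rbind, rows)
    write_tsv_report(tab, file.path(cfg$outdir, "mismatch.tsv"), cfg, "mismatch")
    tab
  })

  if ("demography" %in% stages) run_stage("demography", {
    out <- list()
    for (sp in cfg$species) {
      filt <- lapply(names(alns), function(l)
        infinite_sites_filter(by_sp[[l]][[sp]])$aln)
      names(filt) <- names(alns)
      fit <- fit_three_models(filt, n_genealogy_samples = cfg$mc_samples,
                              theta_max = cfg$theta_max, seed = cfg$seed)
      out[[sp]] <- fit
      jsonlite::write_json(
        list(species = sp, winner = fit$winner,
             lnL = list(M1 = fit$M1$lnL, M2 = fit$M2$lnL, M3 = fit$M3$lnL),
             M2_event = c(T = fit$M2$T_b, S = fit$M2$S_b),
             M3_event = list(T = fit$M3$T_i, S = fit$M3$S_i),
             lrt = fit$lrt, seed = cfg$seed),
        file.path(cfg$outdir, sprintf("demography_%s.json", sp)),
        auto_unbox = TRUE, digits = NA)
    }
    out
  })

  failed <- grepl("^failed", unlist(status))
  structure(list(status = unlist(status), results = results),
            exit_code = if (any(failed)) 3L else 0L)
}

#' Command-line entry point
#'
#' Verbs: `summarize`, `windows`, `ld`, `mk`, `mlhka`, `mismatch`,
#' `demography`, `simulate`, `run-all`. All analysis verbs need
#' `--config <json>`; `simulate` needs `--out <dir>` (plus optional
#' `--seed`). Exit codes: 0 success, 2 validation error, 3 stage failure.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code (invisibly).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: poldiv <verb> [--config cfg.json] [--out dir] [--seed int]"
  if (length(args) < 1) { message(usage); return(invisible(2L)) }
  verb <- args[1]
  opt <- list(config = NULL, out = NULL, seed = 1L)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) { message(usage); return(invisible(2L)) }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  opt$seed <- as.integer(opt$seed)
  if (verb == "simulate") {
    if (is.null(opt$out)) { message("simulate needs --out"); return(invisible(2L)) }
    sim <- simulate_two_species(scenario_spec(seed = opt$seed))
    write_scenario(sim, opt$out)
    return(invisible(0L))
  }
  verbs <- c(summarize = "summarize", windows = "windows", ld = "ld",
             mk = "mk", mlhka = "mlhka", mismatch = "mismatch",
             demography = "demography", `run-all` = NA)
  if (!verb %in% names(verbs)) { message(usage); return(invisible(2L)) }
  if (is.null(opt$config)) { message(verb, " needs --config"); return(invisible(2L)) }
  cfg <- tryCatch(read_run_config(opt$config), error = function(e) e)
  if (inherits(cfg, "error")) {
    message("config validation failed: ", conditionMessage(cfg))
    return(invisible(2L))
  }
  stages <- if (verb == "run-all") eval(formals(run_study)$stages) else verbs[[verb]]
  res <- run_study(cfg, stages)
  for (s in names(res$status)) message(s, ": ", res$status[[s]])
  invisible(attr(res, "exit_code"))
}
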