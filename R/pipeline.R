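CONFIG_KEYS <- list(
  top = c("version", "seed", "output_dir", "generator", "stages"),
  generator = c("sequence", "titration", "dispersion", "itc", "shifts"),
  stages = c("titration", "relaxation", "cpmg", "itc", "conformation",
             "motifs"))

#' Load and validate a YAML run configuration
#'
#' The schema is strict: unknown keys at the top, generator and stages
#' levels are rejected, and a seed is mandatory so that every run is
#' reproducible.
#'
#' @param path YAML file.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), CONFIG_KEYS$top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set a seed")
  for (section in c("generator", "stages")) {
    bad <- setdiff(names(cfg[[section]]), CONFIG_KEYS[[section]])
    if (length(bad))
      stop("unknown ", section, " key(s): ", paste(bad, collapse = ", "))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("run_config", "list"))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

write_run_log <- function(out_dir, cfg, stage = NULL) {
  log <- list(package = "idrbind",
              version = as.character(utils::packageVersion("idrbind")),
              stage = stage, seed = cfg$seed, config_hash = config_hash(cfg))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Generate a full synthetic dataset from a run configuration
#'
#' Runs every generator section present in the config (sequence,
#' titration rates, CPMG dispersion, ITC, shift tables), writing the
#' observables in the package's file formats plus a `truth.json` with all
#' ground-truth parameters, and a run log. Re-running the same config
#' reproduces identical files.
#'
#' @param cfg A [run_config()] (or path to one).
#' @param out_dir Output directory; defaults to the config's
#'   `output_dir`.
#' @return Invisibly, the output directory.
#' @export
run_simulate <- function(cfg, out_dir = cfg$output_dir) {
  if (is.character(cfg)) cfg <- run_config(cfg)
  if (is.null(out_dir)) stop("no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- cfg$generator
  if (is.null(g)) stop("config has no generator section")
  truth <- list(seed = cfg$seed)
  seqrec <- NULL
  if (!is.null(g$sequence)) {
    gs <- gen_sequence(g$sequence$length,
                       placements = g$sequence$placements %||% list(),
                       seed = cfg$seed,
                       first_residue_number =
                         g$sequence$first_residue_number %||% 1L)
    seqrec <- gs$sequence
    writeLines(c(paste0(">", seqrec$id), seqrec$residues),
               file.path(out_dir, "sequence.fasta"))
    truth$sequence <- gs$truth
  }
  if (!is.null(g$titration)) {
    gt <- g$titration
    design <- titration_design(
      gt$a_total,
      data.frame(label = vapply(gt$points, `[[`, character(1), "label"),
                 b = vapply(gt$points, function(p) as.character(p$b),
                            character(1))),
      gt$partner_id %||% "partner")
    kd_map <- unlist(gt$kd_sites)
    rates <- gen_titration_rates(seqrec, kd_map, design,
                                 r_free = gt$r_free %||% 3,
                                 r_bound = gt$r_bound %||% 30,
                                 noise_sd = gt$noise_sd %||% 0.02,
                                 seed = cfg$seed + 1)
    write_results(list(rates = rates$rates), out_dir)
    utils::write.csv(data.frame(label = design$points$label,
                                b = design$points$b_total),
                     file.path(out_dir, "design.csv"), row.names = FALSE)
    truth$titration <- rates$truth
  }
  if (!is.null(g$dispersion)) {
    gd <- g$dispersion
    disp <- gen_dispersion(unlist(gd$dw_map), gd$k_ex, gd$p_b,
                           fields = unlist(gd$fields) %||% c(600, 850),
                           r2_0 = gd$r2_0 %||% 8,
                           noise_sd = gd$noise_sd %||% 0.5,
                           seed = cfg$seed + 2)
    df <- disp$data
    names(df)[names(df) == "residue_number"] <- "residue"
    write_results(list(dispersion = as.data.frame(df)), out_dir)
    truth$dispersion <- disp$truth
  }
  if (!is.null(g$itc)) {
    gi <- g$itc
    itc <- gen_itc(n = gi$n %||% 1, kd = gi$kd %||% 5.1,
                   dh = gi$dh %||% -10,
                   cell_conc = gi$cell_conc %||% 30,
                   syringe_conc = gi$syringe_conc %||% 300,
                   cell_volume = gi$cell_volume %||% 200,
                   n_injections = gi$n_injections %||% 19,
                   injection_volume = gi$injection_volume %||% 2,
                   noise_sd = gi$noise_sd %||% 0.01,
                   seed = cfg$seed + 3)
    con <- file.path(out_dir, "itc.csv")
    writeLines(c(sprintf("# cell_conc_uM: %g", itc$data$cell_conc),
                 sprintf("# syringe_conc_uM: %g", itc$data$syringe_conc),
                 sprintf("# cell_volume_uL: %g", itc$data$cell_volume),
                 "volume_uL,heat_ucal",
                 sprintf("%.10g,%.10g", itc$data$injections$volume_uL,
                         itc$data$injections$heat_ucal)), con)
    truth$itc <- itc$truth
  }
  if (!is.null(g$shifts)) {
    gh <- g$shifts
    helix <- lapply(gh$helix_spec %||% list(), function(h)
      list(range = unlist(h$range), population = h$population))
    sh <- gen_shift_tables(seqrec, helix_spec = helix,
                           noise_sd = gh$noise_sd %||% 0.02,
                           seed = cfg$seed + 4)
    write_results(list(shifts = as.data.frame(sh$shifts)), out_dir)
    truth$shifts <- sh$truth
  }
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_log(out_dir, cfg, stage = "simulate")
  invisible(out_dir)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run one analysis stage on a simulated or assembled dataset directory
#'
#' Reads the stage's inputs from `data_dir` (the layout written by
#' [run_simulate()]), executes the corresponding fitting/analysis
#' functions, and writes the stage results plus a run log into
#' `out_dir`.
#'
#' @param cfg A [run_config()] (or path).
#' @param stage One of `"relaxation"`, `"cpmg"`, `"itc"`, `"conformation"`,
#'   `"motifs"`.
#' @param data_dir Dataset directory.
#' @param out_dir Results directory (default `data_dir`/results).
#' @return Invisibly, a list with the stage's main result object.
#' @export
run_fit <- function(cfg, stage, data_dir,
                    out_dir = file.path(data_dir, "results")) {
  if (is.character(cfg)) cfg <- run_config(cfg)
  stage <- match.arg(stage, CONFIG_KEYS$stages)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- cfg$stages[[stage]] %||% list()
  need <- function(f) {
    p <- file.path(data_dir, f)
    if (!file.exists(p)) stop("stage '", stage, "' needs missing input: ", f)
    p
  }
  result <- switch(stage,
    relaxation = {
      rates <- read_results_tsv(need("rates.tsv"))
      des <- utils::read.csv(need("design.csv"))
      design <- titration_design(sc$a_total %||% cfg$generator$titration$a_total,
                                 data.frame(label = des$label, b = des$b))
      prof <- site_kd_profile(rates, design, r_bound = sc$r_bound %||% 30,
                              residues = sc$residues,
                              n_mc = sc$n_mc %||% 500, seed = cfg$seed + 10)
      write_results(list(site_kd = prof), out_dir)
      prof
    },
    cpmg = {
      disp <- read_dispersion_table(need("dispersion.tsv"))
      fit <- global_fit(disp, a_total = sc$a_total, b_total = sc$b_total)
      write_results(list(
        exchange_fit = list(k_ex = fit$k_ex, k_ex_se = fit$k_ex_se,
                            p_b = fit$p_b, p_b_se = fit$p_b_se,
                            chisq = fit$chisq, derived = fit$derived,
                            dw = fit$dw, flags = fit$flags),
        dispersion_fitted = fitted_dispersion(fit)), out_dir)
      fit
    },
    itc = {
      itc <- read_itc_table(need("itc.csv"))
      fit <- fit_itc(itc)
      write_results(list(itc_fit = list(n = fit$n, kd = fit$kd, dh = fit$dh,
                                        offset = fit$offset,
                                        kd_se = fit$kd_se,
                                        c_value = fit$c_value),
                         itc_isotherm = fit$isotherm), out_dir)
      fit
    },
    conformation = {
      shifts <- read_results_tsv(need("shifts.tsv"))
      tab <- shift_table(shifts$residue_number, shifts$residue_type,
                         shifts$atom, shifts$shift)
      seqrec <- read_sequence(need("sequence.fasta"),
                              cfg$generator$sequence$first_residue_number %||% 1L)
      scs <- compute_scs(tab, seqrec)
      ssp <- compute_ssp(scs, window = sc$window %||% 5)
      write_results(list(scs = scs, ssp = ssp), out_dir)
      list(scs = scs, ssp = ssp)
    },
    motifs = {
      seqrec <- read_sequence(need("sequence.fasta"),
                              cfg$generator$sequence$first_residue_number %||% 1L)
      hits <- scan_motifs(seqrec)
      out <- list(motif_hits = hits)
      rates_path <- file.path(data_dir, "rates.tsv")
      if (file.exists(rates_path)) {
        rates <- read_results_tsv(rates_path)
        ref_lab <- rates$point_label[which.min(rates$b_total)]
        top_lab <- rates$point_label[which.max(rates$b_total)]
        ref <- rates[rates$point_label == ref_lab, ]
        top <- rates[rates$point_label == top_lab, ]
        inc <- stats::setNames(top$r1rho - ref$r1rho[
          match(top$residue_number, ref$residue_number)],
          top$residue_number)
        rts <- stats::setNames(top$r1rho, top$residue_number)
        win <- extract_windows(inc, rts, seqrec,
                               min_prominence = sc$min_prominence %||% 2)
        out$windows <- win
        if (nrow(win)) {
          rl <- rank_and_logo(win)
          out$windows <- rl$ranked
          out$pfm <- as.data.frame(rl$pfm)
        }
      }
      write_results(out, out_dir)
      out
    },
    stop("stage '", stage, "' has no runnable implementation here"))
  write_run_log(out_dir, cfg, stage = stage)
  invisible(result)
}

#' Consolidate stage results into a single report
#'
#' Collects whatever stage outputs exist in a results directory into one
#' JSON report plus a human-readable per-residue summary table; stages
#' that were not run are marked absent. Regenerating the report from the
#' same inputs yields identical bytes.
#'
#' @param results_dir Directory with stage outputs.
#' @return The report list, invisibly; writes `report.json` and
#'   `report.tsv`.
#' @export
run_report <- function(results_dir) {
  files <- list.files(results_dir)
  if (!length(files)) stop("results directory is empty: ", results_dir)
  have <- function(f) file.exists(file.path(results_dir, f))
  report <- list(stages_present = character(0), stages_absent = character(0))
  rows <- list()
  if (have("site_kd.tsv")) {
    kd <- read_results_tsv(file.path(results_dir, "site_kd.tsv"))
    report$stages_present <- c(report$stages_present, "relaxation")
    report$site_kd <- kd
    rows$kd <- data.frame(residue_number = kd$residue_number,
                          site_kd_uM = kd$kd_uM)
  } else report$stages_absent <- c(report$stages_absent, "relaxation")
  if (have("exchange_fit.json")) {
    ex <- jsonlite::read_json(file.path(results_dir, "exchange_fit.json"),
                              simplifyVector = TRUE)
    report$stages_present <- c(report$stages_present, "cpmg")
    report$exchange <- ex
  } else report$stages_absent <- c(report$stages_absent, "cpmg")
  if (have("itc_fit.json")) {
    report$stages_present <- c(report$stages_present, "itc")
    report$itc <- jsonlite::read_json(file.path(results_dir, "itc_fit.json"),
                                      simplifyVector = TRUE)
  } else report$stages_absent <- c(report$stages_absent, "itc")
  if (have("motif_hits.tsv")) {
    report$stages_present <- c(report$stages_present, "motifs")
    report$motifs <- read_results_tsv(file.path(results_dir,
                                                "motif_hits.tsv"))
  } else report$stages_absent <- c(report$stages_absent, "motifs")
  if (have("ssp.tsv")) {
    report$stages_present <- c(report$stages_present, "conformation")
    ssp <- read_results_tsv(file.path(results_dir, "ssp.tsv"))
    report$ssp <- ssp
  } else report$stages_absent <- c(report$stages_absent, "conformation")

  summary_tab <- NULL
  if (length(rows)) {
    summary_tab <- rows$kd
    if (!is.null(report$motifs) && nrow(report$motifs)) {
      m <- report$motifs
      lab <- vapply(summary_tab$residue_number, function(r) {
        hit <- m$motif_class[m$start <= r & m$end >= r]
        if (length(hit)) paste(unique(hit), collapse = ",") else ""
      }, character(1))
      summary_tab$motif <- lab
    }
  }
  jsonlite::write_json(report, file.path(results_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(summary_tab))
    utils::write.table(summary_tab, file.path(results_dir, "report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(report)
}
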