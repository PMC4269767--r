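## Orchestration: TSV conventions, study configuration and the end-to-end
## apo-versus-bound comparison report. All tabular I/O is TSV with a
## one-line header, UTF-8 and '.' decimals, so outputs diff cleanly and
## reruns are bit-identical. Progress/log messages go to stderr via
## message(); results are never mixed into logs.

#' Read/write pipeline tables
#'
#' Thin TSV wrappers with column validation for the pipeline's table
#' kinds: dispersion (`residue`, `field`, `nu_cpmg`, `r2eff`,
#' `r2eff_err`), relaxation rates (`residue`, `field`, `r1`, `r2`, `noe`
#' plus optional error columns), decays (`residue`, `x`, `intensity`,
#' optional `err`) and shift tables (`residue` plus any of `h`, `n`, `co`,
#' `ca`, `cb`).
#'
#' @param path TSV file.
#' @param data data.frame to write.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_dispersion_tsv <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("residue", "field", "nu_cpmg", "r2eff") %in% names(d)))
  d
}

#' @rdname pipeline_io
#' @export
write_dispersion_tsv <- function(data, path) .write_tsv(data, path)

#' @rdname pipeline_io
#' @export
read_rates_tsv <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("residue", "field", "r1", "r2", "noe") %in% names(d)))
  d
}

#' @rdname pipeline_io
#' @export
write_rates_tsv <- function(data, path) .write_tsv(data, path)

#' @rdname pipeline_io
#' @export
read_decays_tsv <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("residue", "x", "intensity") %in% names(d)))
  d
}

#' @rdname pipeline_io
#' @export
write_decays_tsv <- function(data, path) .write_tsv(data, path)

#' @rdname pipeline_io
#' @export
read_shift_table <- function(path) {
  d <- .read_tsv(path)
  stopifnot("residue" %in% names(d))
  if (!any(.shift_nuclei %in% names(d))) {
    stop("shift table has no shift columns (h, n, co, ca, cb)")
  }
  d
}

#' @rdname pipeline_io
#' @export
write_shift_table <- function(data, path) .write_tsv(data, path)

#' Import a BMRB-style two-column assignment list
#'
#' Adapter for the common flat export of deposited assignments: one row
#' per shift with columns `residue`, `atom` (e.g. "H", "N", "C", "CA",
#' "CB") and `shift` (ppm). Returns the wide per-residue shift table the
#' pipeline uses.
#'
#' @param path TSV with columns `residue`, `atom`, `shift`.
#' @return shift table data.frame (`residue`, `h`, `n`, `co`, `ca`, `cb`).
#' @export
read_bmrb_shifts <- function(path) {
  d <- .read_tsv(path)
  stopifnot(all(c("residue", "atom", "shift") %in% names(d)))
  map <- c(H = "h", HN = "h", N = "n", C = "co", CO = "co",
           CA = "ca", CB = "cb")
  d$col <- map[toupper(d$atom)]
  d <- d[!is.na(d$col), ]
  out <- data.frame(residue = sort(unique(d$residue)))
  for (cc in c("h", "n", "co", "ca", "cb")) {
    di <- d[d$col == cc, ]
    out[[cc]] <- di$shift[match(out$residue, di$residue)]
  }
  out
}

#' Study configuration for the apo-versus-bound comparison
#'
#' Collects per-sample input tables (in memory or as TSV paths) and stage
#' parameters for [run_compare()]. Every element is optional; stages whose
#' inputs are missing are skipped and marked absent in the report.
#'
#' @param apo,bound per-sample input lists with any of: `rates`
#'   (relaxation set), `dispersion`, `diffusion` (decays with a `residue`
#'   column, squared-gradient `x`), `diffusion_reference` (reference
#'   decay), `shifts` (shift table). Each entry may be a data.frame or a
#'   TSV path.
#' @param params stage parameters: `fields`, `flat_alpha` (default 0.01),
#'   `n_mc` (default 100), `n_best` (default 20), `seed`, `noe_cutoff`,
#'   `std` (shift normalisation factors), `dispersion_model`.
#' @return object of class `"study_config"`.
#' @export
study_config <- function(apo = list(), bound = list(), params = list()) {
  defaults <- list(flat_alpha = 0.01, n_mc = 100, n_best = 20, seed = 1,
                   noe_cutoff = 0.65, std = bmrb_shift_sd,
                   dispersion_model = "cr")
  params <- utils::modifyList(defaults, params)
  stopifnot(is.numeric(params$seed))
  structure(list(apo = apo, bound = bound, params = params),
            class = "study_config")
}

.load_table <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    if (!file.exists(x)) stop("input file not found: ", x)
    reader(x)
  } else x
}

#' Run the apo-versus-bound comparison
#'
#' Executes every analysis stage for which inputs are present in both
#' samples and assembles the comparison report: per-residue order
#' parameter changes (bound - apo), flat/non-flat dispersion counts per
#' sample with the global exchange fit of the apo data, the relative
#' diffusion (Dt ratio) and hydrodynamic radii, the cumulative shift
#' difference profile, and the correlation between dispersion-derived and
#' binding 15N shift differences. Stage failures are isolated: a failing
#' stage is reported in `$errors` and the remaining stages complete.
#'
#' @param config a [study_config()].
#' @param outdir optional directory; when given, every result table is
#'   written there as TSV.
#' @return object of class `"compare_report"` (a list of stage results).
#' @export
run_compare <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "study_config"))
  p <- config$params
  report <- list(params = p, seed = p$seed, errors = list())
  note <- function(stage, e) {
    message("stage '", stage, "' failed: ", conditionMessage(e))
    report$errors[[stage]] <<- conditionMessage(e)
  }

  ## --- model-free stage -------------------------------------------------
  rates_a <- .load_table(config$apo[["rates"]], read_rates_tsv)
  rates_b <- .load_table(config$bound[["rates"]], read_rates_tsv)
  if (!is.null(rates_a) && !is.null(rates_b)) {
    tryCatch({
      tc_a <- fit_tc(rates_a, noe_cutoff = p$noe_cutoff)
      tc_b <- fit_tc(rates_b, noe_cutoff = p$noe_cutoff)
      mf_a <- fit_modelfree(rates_a, tc_a$tau_c_ns)
      mf_b <- fit_modelfree(rates_b, tc_b$tau_c_ns)
      s2 <- merge(mf_a$residues[, c("residue", "s2")],
                  mf_b$residues[, c("residue", "s2")],
                  by = "residue", suffixes = c("_apo", "_bound"))
      s2$delta_s2 <- s2$s2_bound - s2$s2_apo
      report$modelfree <- list(tau_c_apo_ns = tc_a$tau_c_ns,
                               tau_c_bound_ns = tc_b$tau_c_ns,
                               s2 = s2, fit_apo = mf_a, fit_bound = mf_b)
    }, error = function(e) note("modelfree", e))
  } else message("model-free stage skipped (rates missing)")

  ## --- dispersion stage -------------------------------------------------
  disp_a <- .load_table(config$apo[["dispersion"]], read_dispersion_tsv)
  disp_b <- .load_table(config$bound[["dispersion"]], read_dispersion_tsv)
  flat_counts <- function(d) {
    res <- sort(unique(d$residue))
    flags <- vapply(res, function(r) {
      di <- d[d$residue == r, ]
      f <- di$field[1]
      di <- di[di$field == f, ]
      detect_flat(di$nu_cpmg, di$r2eff, di$r2eff_err,
                  alpha = p$flat_alpha)$flat
    }, logical(1))
    data.frame(residue = res, flat = flags)
  }
  if (!is.null(disp_a)) {
    tryCatch({
      fa <- flat_counts(disp_a)
      report$dispersion <- list(
        apo_flat = fa, apo_n_nonflat = sum(!fa$flat))
      sel <- fa$residue[!fa$flat]
      if (length(sel) >= 2) {
        fit <- fit_dispersion(disp_a, residues = sel,
                              model = p$dispersion_model,
                              n_mc = p$n_mc, seed = p$seed)
        report$dispersion$fit_apo <- fit
        report$dispersion$tau_ex_ms <- fit$tau_ex_ms
      }
    }, error = function(e) note("dispersion_apo", e))
  }
  if (!is.null(disp_b)) {
    tryCatch({
      fb <- flat_counts(disp_b)
      report$dispersion$bound_flat <- fb
      report$dispersion$bound_n_nonflat <- sum(!fb$flat)
    }, error = function(e) note("dispersion_bound", e))
  }
  if (is.null(disp_a) && is.null(disp_b)) {
    message("dispersion stage skipped (no dispersion inputs)")
  }

  ## --- diffusion stage --------------------------------------------------
  diff_stage <- function(decays, reference) {
    res <- sort(unique(decays$residue))
    fits <- lapply(res, function(r) {
      fit_attenuation(data = decays[decays$residue == r, ])
    })
    names(fits) <- res
    agg <- aggregate_best(fits, n = min(p$n_best, length(fits)))
    out <- list(aggregate = agg)
    if (!is.null(reference)) {
      fr <- fit_attenuation(data = reference)
      out$r_h <- hydrodynamic_radius(agg$mean_d, fr$rate)
    }
    out
  }
  dec_a <- .load_table(config$apo[["diffusion"]], read_decays_tsv)
  dec_b <- .load_table(config$bound[["diffusion"]], read_decays_tsv)
  ref_a <- .load_table(config$apo[["diffusion_reference"]], read_decays_tsv)
  ref_b <- .load_table(config$bound[["diffusion_reference"]], read_decays_tsv)
  if (!is.null(dec_a) && !is.null(dec_b)) {
    tryCatch({
      da <- suppressWarnings(diff_stage(dec_a, ref_a))
      db <- suppressWarnings(diff_stage(dec_b, ref_b))
      rel <- relative_diffusion(da$aggregate, db$aggregate)
      report$diffusion <- list(
        apo = da, bound = db,
        dt_ratio = rel$ratio, dt_ratio_err = rel$ratio_err,
        r_h_apo = da$r_h, r_h_bound = db$r_h)
    }, error = function(e) note("diffusion", e))
  } else message("diffusion stage skipped (decays missing); section absent")

  ## --- shifts stage -----------------------------------------------------
  sh_a <- .load_table(config$apo[["shifts"]], read_shift_table)
  sh_b <- .load_table(config$bound[["shifts"]], read_shift_table)
  if (!is.null(sh_a) && !is.null(sh_b)) {
    tryCatch({
      report$shifts <- list(dw_cum = delta_omega_cum(sh_a, sh_b,
                                                     std = p$std))
      if ("n" %in% names(sh_a) && "n" %in% names(sh_b) &&
          !is.null(report$dispersion$fit_apo)) {
        m <- merge(sh_a[, c("residue", "n")], sh_b[, c("residue", "n")],
                   by = "residue", suffixes = c("_a", "_b"))
        dw_bind <- stats::setNames(abs(m$n_b - m$n_a), m$residue)
        fit <- report$dispersion$fit_apo
        dw_disp <- stats::setNames(fit$residues$dw_ppm,
                                   fit$residues$residue)
        report$shifts$correlation <- tryCatch(
          correlate_dw(dw_disp, dw_bind),
          error = function(e) {
            message("dw correlation undefined: ", conditionMessage(e))
            list(r = NA_real_, slope = NA_real_, n = NA_integer_)
          })
      }
    }, error = function(e) note("shifts", e))
  } else message("shifts stage skipped (shift tables missing)")

  class(report) <- "compare_report"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.compare_report <- function(x, ...) {
  cat("Apo-versus-bound comparison report (seed ", x$seed, ")\n", sep = "")
  if (!is.null(x$modelfree)) {
    cat(sprintf("  tau_c: apo %.2f ns -> bound %.2f ns; mean dS2 = %+.3f\n",
                x$modelfree$tau_c_apo_ns, x$modelfree$tau_c_bound_ns,
                mean(x$modelfree$s2$delta_s2, na.rm = TRUE)))
  }
  if (!is.null(x$dispersion)) {
    cat(sprintf("  dispersion: %s non-flat (apo), %s non-flat (bound)",
                x$dispersion$apo_n_nonflat %||% "?",
                x$dispersion$bound_n_nonflat %||% "?"))
    if (!is.null(x$dispersion$tau_ex_ms)) {
      cat(sprintf("; tau_ex = %.2f ms", x$dispersion$tau_ex_ms))
    }
    cat("\n")
  }
  if (!is.null(x$diffusion)) {
    cat(sprintf("  diffusion: Dt_bound/Dt_apo = %.3f +/- %.3f",
                x$diffusion$dt_ratio, x$diffusion$dt_ratio_err))
    if (!is.null(x$diffusion$r_h_apo)) {
      cat(sprintf("; r_h %.1f -> %.1f A", x$diffusion$r_h_apo,
                  x$diffusion$r_h_bound))
    }
    cat("\n")
  }
  if (!is.null(x$shifts)) {
    cat(sprintf("  shifts: max dw_cum = %.3f ppm",
                max(x$shifts$dw_cum$dw_cum, na.rm = TRUE)))
    if (!is.null(x$shifts$correlation)) {
      cat(sprintf("; dw_disp vs dw_bind r = %.2f", x$shifts$correlation$r))
    }
    cat("\n")
  }
  if (length(x$errors)) {
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the comparison report tables as TSV
#'
#' @param report a `compare_report` from [run_compare()].
#' @param outdir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  put <- function(df, name) {
    f <- file.path(outdir, name)
    .write_tsv(df, f)
    paths <<- c(paths, f)
  }
  if (!is.null(report$modelfree)) {
    put(report$modelfree$s2, "s2_compare.tsv")
    mf <- report$modelfree$fit_apo$residues
    put(mf, "modelfree_apo.tsv")
    put(report$modelfree$fit_bound$residues, "modelfree_bound.tsv")
  }
  if (!is.null(report$dispersion)) {
    if (!is.null(report$dispersion$apo_flat)) {
      put(report$dispersion$apo_flat, "dispersion_flat_apo.tsv")
    }
    if (!is.null(report$dispersion$bound_flat)) {
      put(report$dispersion$bound_flat, "dispersion_flat_bound.tsv")
    }
    if (!is.null(report$dispersion$fit_apo)) {
      put(report$dispersion$fit_apo$global, "exchange_global.tsv")
      put(report$dispersion$fit_apo$residues, "exchange_residues.tsv")
      put(report$dispersion$fit_apo$r2_0, "exchange_r2_0.tsv")
    }
  }
  if (!is.null(report$diffusion)) {
    put(data.frame(
      dt_ratio = report$diffusion$dt_ratio,
      dt_ratio_err = report$diffusion$dt_ratio_err,
      r_h_apo = report$diffusion$r_h_apo %||% NA,
      r_h_bound = report$diffusion$r_h_bound %||% NA,
      seed = report$seed), "diffusion_compare.tsv")
  }
  if (!is.null(report$shifts)) {
    put(report$shifts$dw_cum, "dw_cum.tsv")
    if (!is.null(report$shifts$correlation)) {
      put(data.frame(r = report$shifts$correlation$r,
                     slope = report$shifts$correlation$slope,
                     n = report$shifts$correlation$n), "dw_correlation.tsv")
    }
  }
  invisible(paths)
}
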