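#' Read an MSMC2-style final rate table
#'
#' Reads the tab-separated `.final.txt` dialect with header
#' `time_index left_time_boundary right_time_boundary lambda_00 lambda_01
#' lambda_11` (cross-population mode) or with a single `lambda` column
#' (within-population mode), all in mutation-scaled units, and converts to
#' generations and per-generation hazards: `t_gen = t_scaled / mu` and
#' `h = lambda_scaled * mu` (so `N = (1/lambda_scaled) / (2 mu)`).
#'
#' @param path File path.
#' @param scaling A [scaling_config()].
#' @return A [rate_curves()] tibble in per-generation units; in
#'   within-population mode the single curve fills `lambda_11` and the
#'   other columns are `NA`.
#' @export
read_msmc2_final <- function(path, scaling = scaling_config()) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  cross <- all(c("lambda_00", "lambda_01", "lambda_11") %in% names(raw))
  within <- "lambda" %in% names(raw)
  need <- c("time_index", "left_time_boundary", "right_time_boundary")
  if (!all(need %in% names(raw)) || !(cross || within)) {
    stop("not an MSMC2 final table: ", path, call. = FALSE)
  }
  bad <- which(!stats::complete.cases(raw[need]) |
                 raw$left_time_boundary >= raw$right_time_boundary)
  if (length(bad)) {
    stop("malformed rows (after header) at line(s): ",
         paste(bad + 1, collapse = ", "), call. = FALSE)
  }
  left <- raw$left_time_boundary / scaling$mu
  right <- raw$right_time_boundary / scaling$mu
  if (left[1] <= 0) left[1] <- min(1, right[1] / 2)  # log-grid-safe origin
  conv <- function(x) x * scaling$mu
  if (cross) {
    rate_curves(left, right, conv(raw$lambda_00), conv(raw$lambda_01),
                conv(raw$lambda_11), units = "generations")
  } else {
    rate_curves(left, right, conv(raw$lambda), NA_real_, NA_real_,
                units = "generations")
  }
}

#' Write rate curves as an MSMC2-style final table
#'
#' Inverse of [read_msmc2_final()]: converts per-generation curves back to
#' mutation-scaled units and writes the tab-separated cross-population
#' dialect.
#'
#' @param rates A [rate_curves()] tibble in per-generation units.
#' @param path Output path.
#' @param scaling A [scaling_config()].
#' @export
write_msmc2_final <- function(rates, path, scaling = scaling_config()) {
  stopifnot(identical(attr(rates, "units"), "generations"))
  out <- data.frame(
    time_index = seq_len(nrow(rates)) - 1,
    left_time_boundary = rates$left * scaling$mu,
    right_time_boundary = rates$right * scaling$mu,
    lambda_00 = rates$lambda_11 / scaling$mu,
    lambda_01 = rates$lambda_12 / scaling$mu,
    lambda_11 = rates$lambda_22 / scaling$mu
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fitted trajectory as an estimate table
#'
#' Five tab-separated columns `time m M im_N1 im_N2` with times in years
#' (left interval boundaries) and the cumulative migration probability at
#' those boundaries.
#'
#' @param traj An [im_trajectory()] (or an `im_fit`, whose trajectory is
#'   used).
#' @param path Output path.
#' @param scaling A [scaling_config()].
#' @export
write_estimate <- function(traj, path, scaling = scaling_config()) {
  if (inherits(traj, "im_fit")) traj <- traj$trajectory
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  M <- traj_M(traj)
  out <- data.frame(time = traj$left * scaling$g, m = traj$m,
                    M = M[-length(M)], im_N1 = traj$im_N1,
                    im_N2 = traj$im_N2)
  utils::write.table(format(out, digits = 15, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an estimate table back into a trajectory
#'
#' @param path File written by [write_estimate()].
#' @param scaling The [scaling_config()] used when writing.
#' @return An [im_trajectory()] (times in generations). The oldest
#'   interval's right boundary is not stored in the file and is
#'   reconstructed by extending the last log-time step.
#' @export
read_estimate <- function(path, scaling = scaling_config()) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time", "m", "M", "im_N1", "im_N2") %in% names(raw)),
            !is.unsorted(raw$time, strictly = TRUE),
            !is.unsorted(raw$M))
  left <- raw$time / scaling$g
  k <- length(left)
  last_right <- exp(log(left[k]) + (log(left[k]) - log(left[k - 1])))
  im_trajectory(c(left, last_right), m = raw$m, N1 = raw$im_N1,
                N2 = raw$im_N2)
}

#' Write coalescence-time draws as a tab-separated table
#'
#' @param samples A `tmrca_sample` tibble.
#' @param path Output path.
#' @export
write_tmrca <- function(samples, path) {
  utils::write.table(as.data.frame(samples)[c("time", "censored", "start",
                                              "block")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tmrca
#' @export
read_tmrca <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- tibble::as_tibble(raw[c("time", "censored", "start", "block")])
  class(out) <- c("tmrca_sample", class(out))
  out
}

#' Read a biallelic genotype panel from a VCF file
#'
#' Keeps biallelic records carrying a GT field; multiallelic or GT-less
#' records are skipped with a message. Phased (`|`) and unphased (`/`)
#' separators are both accepted; `./.` is missing.
#'
#' @param path VCF path (plain text or gzipped).
#' @param sample_regions Optional data frame `sample`, `region` assigning
#'   samples to regions (default: one region `"all"`).
#' @return A `genotype_panel`.
#' @export
read_vcf <- function(path, sample_regions = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt) & alt != "."
  has_gt <- "GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID ||
    any(grepl("GT", v@gt[, 1]))
  if (!has_gt) stop("VCF has no GT field", call. = FALSE)
  skipped <- sum(!biallelic)
  if (skipped > 0) {
    message(skipped, " non-biallelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v[biallelic, ], element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_integer_, length(x))
    clean <- gsub("\\|", "/", x)
    out[clean == "0/0"] <- 0L
    out[clean %in% c("0/1", "1/0")] <- 1L
    out[clean == "1/1"] <- 2L
    out
  }
  geno <- t(apply(gt, 2, count_alt))
  ids <- colnames(gt)
  rownames(geno) <- ids
  if (is.null(sample_regions)) {
    sample_regions <- tibble::tibble(sample = ids, region = "all")
  }
  samples <- dplyr::left_join(tibble::tibble(sample = ids), sample_regions,
                              by = "sample")
  ord <- order(fix[biallelic, "CHROM"],
               as.numeric(fix[biallelic, "POS"]))
  genotype_panel(
    geno = geno[, ord, drop = FALSE],
    map = tibble::tibble(chrom = fix[biallelic, "CHROM"][ord],
                         pos = as.numeric(fix[biallelic, "POS"][ord])),
    samples = samples
  )
}

#' Write a genotype panel as a minimal GT-only VCF
#'
#' Plain-text VCF 4.2 with a GT FORMAT field only; alleles are written as
#' A (reference) and T (alternate) placeholders.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @export
write_vcf_panel <- function(panel, path) {
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  geno <- panel$geno
  body <- vapply(seq_len(ncol(geno)), function(j) {
    calls <- ifelse(is.na(geno[, j]), "./.", gt_str[as.character(geno[, j])])
    paste(c(panel$map$chrom[j], panel$map$pos[j], ".", "A", "T", ".",
            "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Bundle and serialize a full pipeline configuration
#'
#' Collects the time scaling, fit, ROH and period settings plus grid and
#' seed choices into one object that round-trips losslessly through YAML,
#' so that an analysis is reproducible from its configuration file alone.
#'
#' @param scaling A [scaling_config()].
#' @param fit A [fit_config()].
#' @param roh A [roh_params()].
#' @param periods A [period_catalog()].
#' @param grid_n,grid_from,grid_to Time-grid settings (see [time_grid()]).
#' @param seed Base seed recorded for the run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(scaling = scaling_config(), fit = fit_config(),
                            roh = roh_params(), periods = period_catalog(),
                            grid_n = 64, grid_from = 10, grid_to = 2e6,
                            seed = 1) {
  structure(list(scaling = unclass(scaling), fit = unclass(fit),
                 roh = unclass(roh),
                 periods = as.data.frame(periods),
                 grid = list(n = grid_n, from = grid_from, to = grid_to),
                 seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  pc <- pipeline_config(
    scaling = do.call(scaling_config, raw$scaling),
    fit = do.call(fit_config, raw$fit),
    roh = do.call(roh_params, raw$roh),
    periods = {
      pd <- as.data.frame(do.call(cbind.data.frame, raw$periods))
      period_catalog(mis8 = unlist(pd[pd$period == "MIS8", c("young", "old")]),
                     mis10 = unlist(pd[pd$period == "MIS10", c("young", "old")]))
    },
    grid_n = raw$grid$n, grid_from = raw$grid$from, grid_to = raw$grid$to,
    seed = raw$seed
  )
  pc
}
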