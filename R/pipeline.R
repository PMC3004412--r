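#' Read and validate a pipeline run configuration
#'
#' A run configuration is a single YAML (or JSON) document describing which
#' stages to execute and the parameters of each. The schema is strict:
#' unknown keys, at the top level or inside a stage section, are rejected
#' before anything runs.
#'
#' Recognised top-level keys: `stages` (ordered subset of `simulate`,
#' `degrade`, `denoise`, `reconstruct`, `evaluate`), `seed`, `output_dir`,
#' and one optional section per stage.
#'
#' @param path path to a YAML/JSON config file, or a list with the same
#'   structure.
#' @return a validated config list of class `run_config`, carrying a
#'   `params_digest` attribute (a stable hash of the parameters).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  validate_run_config(cfg)
}

stage_keys <- list(
  simulate = c("shape", "factors", "noise_pct", "n_structures",
               "pv_smoothing_sigma", "lesion", "boundary_mode"),
  degrade = c("input", "factors", "boundary_mode"),
  denoise = c("sigma", "search_radius", "patch_radius", "beta"),
  reconstruct = c("lr", "ref", "factors", "boundary_mode", "h", "k", "tol",
                  "search_radius", "patch_radius", "init", "max_iters",
                  "out", "save_state"),
  evaluate = c("truth", "test", "baselines", "peak", "report")
)

validate_run_config <- function(cfg) {
  top_known <- c("stages", "seed", "output_dir", names(stage_keys))
  unknown <- setdiff(names(cfg), top_known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$stages)) stop("config must list `stages`", call. = FALSE)
  cfg$stages <- as.character(unlist(cfg$stages))
  bad <- setdiff(cfg$stages, names(stage_keys))
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (st in names(stage_keys)) {
    if (!is.null(cfg[[st]])) {
      unknown <- setdiff(names(cfg[[st]]), stage_keys[[st]])
      if (length(unknown) > 0) {
        stop(sprintf("unknown key(s) in `%s` section: %s", st,
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  attr(cfg, "params_digest") <- params_digest(cfg)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Stable digest of a parameter set
#'
#' FNV-1a hash over the serialised canonical form of a list; used to stamp
#' reports and output provenance so a run can be re-identified and
#' re-executed bit-identically (for the deterministic stages).
#'
#' @param x any serialisable R object.
#' @return a 16-character hex string.
#' @export
params_digest <- function(x) {
  attr(x, "params_digest") <- NULL
  if (is.list(x)) {
    cls <- class(x)
    x <- x[order(names(x))]
    class(x) <- setdiff(cls, "run_config")
  }
  bytes <- as.integer(serialize(x, NULL, version = 2, xdr = TRUE))
  # 32-bit FNV-1a kept exact in doubles (xor touches only the low byte;
  # the modular multiply is split into 16-bit halves); run once forward
  # and once reversed for a 64-bit-wide digest
  fnv32 <- function(bs) {
    h <- 2166136261
    for (b in bs) {
      h <- h - (h %% 256) + bitwXor(h %% 256, b)
      h0 <- h %% 65536; h1 <- h %/% 65536
      h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
    }
    h
  }
  hex32 <- function(h) sprintf("%04x%04x", as.integer(h %/% 65536),
                               as.integer(h %% 65536))
  paste0(hex32(fnv32(bytes)), hex32(fnv32(rev(bytes))))
}

pipe_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
  invisible(NULL)
}

#' Run a configured pipeline
#'
#' Executes the configured stages in order (`simulate` / `degrade` /
#' `denoise` / `reconstruct` / `evaluate`), passing volumes between stages
#' in memory and optionally on disk. Per-stage timing and parameters are
#' logged; the `evaluate` stage returns (and optionally writes) a report
#' with one PSNR entry per method, stamped with the parameter digest.
#'
#' @param config a config path or list accepted by [read_run_config()].
#' @param verbose log stage progress (default `TRUE`).
#' @return the report list (invisibly for non-evaluate runs): elements
#'   `psnr` (named list of dB values), `state` (reconstruction state, when
#'   run), `params_digest`, `seed`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  cfg <- read_run_config(config)
  seed <- cfg$seed
  out_dir <- cfg$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  env <- new.env(parent = emptyenv())
  report <- list(params_digest = attr(cfg, "params_digest"), seed = seed)

  for (st in cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    sc <- cfg[[st]] %||% list()
    switch(st,
      simulate = {
        dspec <- degradation_spec(sc$factors %||% c(1, 1, 2),
                                  sc$boundary_mode %||% "strict")
        pspec <- phantom_spec(shape = sc$shape %||% c(64, 64, 64),
                              n_structures = sc$n_structures %||% 5L,
                              pv_smoothing_sigma = sc$pv_smoothing_sigma %||% 0.8,
                              lesion = sc$lesion, seed = seed)
        noise <- rician_noise_spec(percent_of_max = sc$noise_pct %||% 0,
                                   seed = seed)
        env$bundle <- simulate_study(pspec, dspec, noise)
        env$dspec <- dspec
        env$lr <- env$bundle$lr_input
        env$ref <- env$bundle$hr_reference
        env$truth <- env$bundle$hr_truth
        if (!is.null(out_dir)) {
          write_volume(env$truth, file.path(out_dir, "hr_truth.nii.gz"))
          write_volume(env$ref, file.path(out_dir, "hr_reference.nii.gz"))
          write_volume(env$lr, file.path(out_dir, "lr_input.nii.gz"))
        }
      },
      degrade = {
        x <- if (!is.null(sc$input)) read_volume(sc$input) else env$truth
        if (is.null(x)) stop("degrade: no input volume", call. = FALSE)
        dspec <- degradation_spec(sc$factors %||% c(1, 1, 2),
                                  sc$boundary_mode %||% "strict")
        env$dspec <- dspec
        env$lr <- boxcar_downsample(x, dspec)
        if (!is.null(out_dir)) {
          write_volume(env$lr, file.path(out_dir, "lr_input.nii.gz"))
        }
      },
      denoise = {
        if (is.null(env$lr)) stop("denoise: no LR volume in scope", call. = FALSE)
        sig <- sc$sigma
        sig_num <- if (is.null(sig) || identical(sig, "auto")) NULL else as.numeric(sig)
        dp <- denoise_params(search_radius = sc$search_radius %||% 3L,
                             patch_radius = sc$patch_radius %||% 1L,
                             sigma = sig_num, beta = sc$beta %||% 1.0)
        env$lr <- nlm_denoise(env$lr, dp)
        if (!is.null(env$ref)) env$ref <- nlm_denoise(env$ref, dp)
      },
      reconstruct = {
        lr <- if (!is.null(sc$lr)) read_volume(sc$lr) else env$lr
        ref <- if (!is.null(sc$ref)) read_volume(sc$ref) else env$ref
        if (is.null(lr) || is.null(ref)) {
          stop("reconstruct: need LR and reference volumes", call. = FALSE)
        }
        dspec <- if (!is.null(sc$factors)) {
          degradation_spec(sc$factors, sc$boundary_mode %||% "strict")
        } else env$dspec
        if (is.null(dspec)) stop("reconstruct: no degradation factors", call. = FALSE)
        pars <- sr_params(search_radius = sc$search_radius %||% 3L,
                          patch_radius = sc$patch_radius %||% 1L,
                          h_schedule = sc$h %||% c(32, 16, 8, 4, 2),
                          k = sc$k %||% 256, tol = sc$tol %||% 0.01,
                          max_iters = sc$max_iters %||% 50L,
                          init_method = sc$init %||% "nearest")
        res <- superresolve(lr, ref, dspec, pars, verbose = verbose)
        env$recon <- res$volume
        report$state <- res$state
        if (!is.null(sc$out)) write_volume(res$volume, sc$out)
        else if (!is.null(out_dir)) {
          write_volume(res$volume, file.path(out_dir, "reconstruction.nii.gz"))
        }
        if (!is.null(sc$save_state)) {
          jsonlite::write_json(res$state, sc$save_state, auto_unbox = TRUE,
                               digits = NA)
        }
      },
      evaluate = {
        truth <- if (!is.null(sc$truth)) read_volume(sc$truth) else env$truth
        if (is.null(truth)) stop("evaluate: no ground truth", call. = FALSE)
        peak <- if (is.null(sc$peak)) NULL else as.numeric(sc$peak)
        methods <- sc$baselines %||% c("nearest", "bspline")
        psnrs <- list()
        if (!is.null(env$lr) && !is.null(env$dspec)) {
          for (mth in methods) {
            up <- interpolate_upsample(env$lr, env$dspec, method = mth,
                                       out_dim = dim(truth$data))
            psnrs[[mth]] <- psnr(truth, up, peak)
          }
        }
        test <- if (!is.null(sc$test)) read_volume(sc$test) else env$recon
        if (!is.null(test)) psnrs$proposed <- psnr(truth, test, peak)
        report$psnr <- psnrs
        if (!is.null(report$psnr$proposed) && !is.null(methods[1]) &&
            !is.null(psnrs[[methods[length(methods)]]])) {
          base <- methods[length(methods)]
          report$ipsnr <- psnrs$proposed - psnrs[[base]]
          report$ipsnr_baseline <- base
        }
        dest <- sc$report %||%
          (if (!is.null(out_dir)) file.path(out_dir, "report.json") else NULL)
        if (!is.null(dest)) {
          jsonlite::write_json(report, dest, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
        }
      }
    )
    pipe_log(verbose, "stage %s done in %.1f s", st,
             proc.time()[["elapsed"]] - t0)
  }
  report
}
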