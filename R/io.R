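BUNDLE_SCHEMA <- 1L

fmt_num <- function(x) sprintf("%.17g", x)

write_idx <- function(idx, path) writeLines(as.character(idx), path)
read_idx <- function(path) as.integer(readLines(path))

#' Write a case bundle
#'
#' Serializes a \code{gk_case} to a directory of plain-text files:
#' \code{case.json} (schema version, grid, dose levels, kernel
#' parameters, seed, checksums) plus one voxel-index file per structure
#' mask and a full-precision CSV of isocenter positions.  The round trip
#' through \code{\link{read_case}} is lossless.
#'
#' @param case a \code{gk_case}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- case$kernels
  masks <- c(list(skull = case$skull),
             setNames(case$targets, paste0("target_", seq_along(case$targets))),
             if (length(case$oars) > 0)
               setNames(case$oars, paste0("oar_", seq_along(case$oars))))
  for (nm in names(masks)) write_idx(which(masks[[nm]]), file.path(dir, paste0(nm, ".idx")))
  iso <- data.frame(x = fmt_num(case$iso[, 1]), y = fmt_num(case$iso[, 2]),
                    z = fmt_num(case$iso[, 3]), target = case$iso_target)
  write.csv(iso, file.path(dir, "isocenters.csv"), row.names = FALSE, quote = FALSE)
  meta <- list(
    schema_version = BUNDLE_SCHEMA, name = case$name,
    grid = list(shape = case$grid$shape, spacing = case$grid$spacing,
                origin = fmt_num(case$grid$origin)),
    n_targets = length(case$targets), n_oars = length(case$oars),
    d_presc = fmt_num(case$d_presc),
    d_oar_max = if (length(case$oars) > 0) fmt_num(case$d_oar_max) else character(0),
    d_ld = fmt_num(case$d_ld), seed = case$seed,
    kernels = list(sigma = fmt_num(k$sigma), amp = fmt_num(k$amp),
                   dirs = apply(k$dirs, 1, fmt_num, simplify = FALSE),
                   kappa = fmt_num(k$kappa), rate_cal = fmt_num(k$rate_cal)),
    units = list(length = "mm", dose = "Gy", time = "min"),
    checksum = list(mask_voxels = vapply(masks, sum, 0),
                    n_iso = nrow(case$iso)))
  jsonlite::write_json(meta, file.path(dir, "case.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a case bundle
#'
#' @param dir bundle directory written by \code{\link{write_case}}.
#' @return a \code{gk_case}.
#' @export
read_case <- function(dir) {
  jf <- file.path(dir, "case.json")
  if (!file.exists(jf)) stop("not a case bundle: missing case.json in ", dir)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != BUNDLE_SCHEMA)
    stop("unsupported case bundle schema version: ",
         if (is.null(meta$schema_version)) "<missing>" else meta$schema_version)
  grid <- voxel_grid(meta$grid$shape, meta$grid$spacing,
                     as.numeric(meta$grid$origin))
  load_mask <- function(nm) {
    f <- file.path(dir, paste0(nm, ".idx"))
    if (!file.exists(f)) stop("truncated case bundle: missing ", nm, ".idx")
    m <- array(FALSE, grid$shape)
    m[read_idx(f)] <- TRUE
    m
  }
  skull <- load_mask("skull")
  targets <- lapply(seq_len(meta$n_targets), function(k) load_mask(paste0("target_", k)))
  oars <- if (meta$n_oars > 0)
    lapply(seq_len(meta$n_oars), function(k) load_mask(paste0("oar_", k))) else list()
  iso_df <- read.csv(file.path(dir, "isocenters.csv"))
  masks <- c(list(skull), targets, oars)
  counts <- vapply(masks, sum, 0)
  if (!isTRUE(all.equal(unname(counts), unname(meta$checksum$mask_voxels))) ||
      nrow(iso_df) != meta$checksum$n_iso)
    stop("case bundle checksum mismatch in ", dir)
  dirs_raw <- meta$kernels$dirs
  dirs <- if (is.matrix(dirs_raw)) {
    matrix(as.numeric(dirs_raw), nrow = nrow(dirs_raw))
  } else {
    do.call(rbind, lapply(dirs_raw, as.numeric))
  }
  kern <- list(sigma = as.numeric(meta$kernels$sigma),
               amp = as.numeric(meta$kernels$amp),
               dirs = dirs,
               kappa = as.numeric(meta$kernels$kappa),
               rate_cal = as.numeric(meta$kernels$rate_cal))
  structure(list(grid = grid, skull = skull, targets = targets, oars = oars,
                 target_centers = NULL, oar_centers = NULL,
                 d_presc = as.numeric(meta$d_presc),
                 d_oar_max = as.numeric(meta$d_oar_max),
                 d_ld = as.numeric(meta$d_ld), kernels = kern,
                 iso = unname(as.matrix(data.frame(
                   x = as.numeric(iso_df$x), y = as.numeric(iso_df$y),
                   z = as.numeric(iso_df$z)))),
                 iso_target = iso_df$target, seed = meta$seed,
                 spec = NULL, name = meta$name,
                 schema_version = meta$schema_version), class = "gk_case")
}

#' Run a full planning experiment
#'
#' End-to-end driver: build (or read) a case, run the two-pass sweep,
#' and write the artifact directory: metrics and Pareto tables (CSV),
#' residual traces (CSV), the sampling-plan record and a JSON log of
#' seeds and configuration.  Fully reproducible from (case seed,
#' config).
#'
#' @param config list with fields \code{case} (a \code{gk_case},
#'   \code{phantom_spec}, or bundle directory), \code{sliders}
#'   (default "3x3"), \code{n_iter}, \code{precision}, \code{seed},
#'   \code{out_dir}.
#' @return the sweep object, invisibly; artifacts in \code{out_dir}.
#' @export
run_experiment <- function(config) {
  cfg <- modifyList(list(sliders = "3x3", n_iter = 3000,
                         precision = "single", seed = 1,
                         out_dir = tempfile("gkpareto_run_")), config)
  case <- cfg$case
  if (inherits(case, "phantom_spec")) case <- make_phantom(case)
  if (is.character(case)) case <- read_case(case)
  stopifnot(inherits(case, "gk_case"))

  sweep <- run_two_pass(case, sliders = cfg$sliders, n_iter = cfg$n_iter,
                        precision = cfg$precision, seed = cfg$seed,
                        densities = cfg$densities, caps = cfg$caps)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sweep$metrics, file.path(cfg$out_dir, "metrics.csv"), row.names = FALSE)
  write.csv(pareto_table(sweep$metrics), file.path(cfg$out_dir, "pareto.csv"),
            row.names = FALSE)
  for (pass in 1:2) {
    tr <- sweep[[paste0("fit", pass)]]$trace
    df <- data.frame(iter = tr$iter, primal = tr$primal, dual = tr$dual)
    write.csv(df, file.path(cfg$out_dir, sprintf("residuals_pass%d.csv", pass)),
              row.names = FALSE)
  }
  write.csv(data.frame(instance = seq_along(sweep$sampling$n_realized),
                       n_desired = sweep$sampling$n_desired,
                       n_realized = sweep$sampling$n_realized,
                       omega = sweep$sampling$omega),
            file.path(cfg$out_dir, "sampling_plan.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("gkpareto")),
         case = case$name, seed = cfg$seed,
         sliders = if (is.data.frame(cfg$sliders))
           sprintf("custom (%d vectors)", nrow(cfg$sliders)) else cfg$sliders,
         n_iter = cfg$n_iter, precision = cfg$precision,
         n_weight_vectors = nrow(sweep$sliders)),
    file.path(cfg$out_dir, "run_log.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(sweep)
}
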