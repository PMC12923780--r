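# float32 NIfTI image carrying the given voxel size in its header
nifti_with_pixdim <- function(data, voxel_size) {
  nd <- length(dim(data))
  hdr <- RNifti::niftiHeader(list(
    dim = c(nd, dim(data), rep(1L, 7L - nd)),
    pixdim = c(1, voxel_size[1:3], rep(1, 4))
  ))
  RNifti::asNifti(data, reference = hdr, datatype = "float")
}

#' Read a DWI volume with its FSL-style gradient table
#'
#' Loads a 4-D NIfTI volume plus whitespace-delimited `bvals` (one row of
#' b-values) and `bvecs` (three rows: x, y, z components, one column per
#' volume). Direction vectors whose norm deviates from 1 by more than 1e-3
#' are an error for b > 0 volumes; deviations within tolerance are
#' renormalised with a warning.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param bval_path,bvec_path Gradient table text files.
#' @return A `dwi_volume` whose `scheme` is a `gradient_scheme`.
#' @export
read_dwi <- function(path, bval_path, bvec_path) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4L) stopf("expected a 4-D DWI volume")
  if (any(!is.finite(data))) stopf("DWI volume contains non-finite values")
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvecs) != 3L) stopf("bvec file must have 3 rows (x, y, z)")
  n <- dim(data)[4]
  if (length(bvals) != n || ncol(bvecs) != n) {
    stopf("gradient table length mismatch: %d b-values, %d directions, %d volumes",
          length(bvals), ncol(bvecs), n)
  }
  bvecs <- t(bvecs)
  norms <- sqrt(rowSums(bvecs^2))
  weighted <- bvals > 0
  off <- weighted & abs(norms - 1) > 1e-8
  if (any(off)) {
    if (any(abs(norms[off] - 1) > 1e-3)) {
      stopf("b > 0 direction norms deviate from 1 by more than 1e-3")
    }
    warning(sprintf("renormalised %d gradient direction(s) with norm != 1",
                    sum(off)), call. = FALSE)
    bvecs[off, ] <- bvecs[off, , drop = FALSE] / norms[off]
  }
  scheme <- structure(
    list(bvals = bvals, bvecs = bvecs, n_volumes = n),
    class = "gradient_scheme"
  )
  validate_scheme(scheme)
  vox <- attr(img, "pixdim")
  if (is.null(vox)) vox <- RNifti::pixdim(img)
  structure(
    list(data = data, scheme = scheme, voxel_size = vox[1:3]),
    class = "dwi_volume"
  )
}

#' Write a DWI volume and its gradient table
#'
#' Data are stored as float32 NIfTI-1 (.nii.gz); `bvals`/`bvecs` follow the
#' FSL convention used by [read_dwi()].
#'
#' @param dwi A `dwi_volume`.
#' @param path,bval_path,bvec_path Output paths.
#' @return `path`, invisibly.
#' @export
write_dwi <- function(dwi, path, bval_path, bvec_path) {
  if (!inherits(dwi, "dwi_volume")) stopf("`dwi` must be a dwi_volume")
  RNifti::writeNifti(nifti_with_pixdim(dwi$data, dwi$voxel_size), path)
  writeLines(paste(format(dwi$scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  bv <- t(dwi$scheme$bvecs)
  writeLines(apply(bv, 1, function(r) {
    paste(format(r, trim = TRUE, digits = 12), collapse = " ")
  }), bvec_path)
  invisible(path)
}

#' Write the six diffusivity maps, S0 and mask as NIfTI
#'
#' Files are named `<prefix>_dxx.nii.gz` ... `<prefix>_dyz.nii.gz`,
#' `<prefix>_s0.nii.gz`, `<prefix>_mask.nii.gz`.
#'
#' @param maps A `diffusivity_maps` object.
#' @param prefix Output path prefix.
#' @param voxel_size Voxel size recorded in the headers.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_maps <- function(maps, prefix, voxel_size = c(1.7, 1.7, 1.7)) {
  if (!inherits(maps, "diffusivity_maps")) {
    stopf("`maps` must be a diffusivity_maps object")
  }
  vols <- c(maps$maps, list(s0 = maps$s0, mask = maps$mask * 1))
  paths <- vapply(names(vols), function(nm) {
    p <- sprintf("%s_%s.nii.gz", prefix, nm)
    RNifti::writeNifti(nifti_with_pixdim(vols[[nm]] * 1, voxel_size), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read ROI definitions from JSON
#'
#' The JSON schema lists axis-aligned boxes per region in 0-based voxel
#' coordinates:
#' `{"projection": [{"center": [x,y,z], "shape": "box", "size": [a,b,c]}],
#'   "association": [...]}`.
#' Multiple boxes per region (e.g. left/right pairs) become a list of masks
#' combined with equal weight by [roi_mean_diffusivities()].
#'
#' @param path JSON file path, or an already-parsed list with the same
#'   structure.
#' @param grid_shape Integer length-3 grid dimensions the masks are built on.
#' @return Named list of logical masks (or lists of masks) for `projection`
#'   and `association`.
#' @export
read_roi_json <- function(path, grid_shape) {
  spec <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    path
  }
  grid_shape <- as.integer(grid_shape)
  build_box <- function(box, region) {
    if (!identical(box$shape, "box")) {
      stopf("ROI '%s': only 'box' shapes are supported", region)
    }
    center <- as.numeric(box$center)   # 0-based
    size <- as.integer(box$size)
    if (length(center) != 3 || length(size) != 3 || any(size < 1)) {
      stopf("ROI '%s': center and size must be 3-vectors, size >= 1", region)
    }
    start <- round(center - (size - 1) / 2) + 1L   # to 1-based
    end <- start + size - 1L
    if (any(start < 1L) || any(end > grid_shape)) {
      stopf("ROI '%s' extends outside the %s grid", region,
            paste(grid_shape, collapse = "x"))
    }
    m <- array(FALSE, dim = grid_shape)
    m[start[1]:end[1], start[2]:end[2], start[3]:end[3]] <- TRUE
    m
  }
  out <- lapply(names(spec), function(region) {
    boxes <- spec[[region]]
    masks <- lapply(boxes, build_box, region = region)
    if (length(masks) == 1L) masks[[1]] else masks
  })
  names(out) <- names(spec)
  if (!all(c("projection", "association") %in% names(out))) {
    stopf("ROI file must define 'projection' and 'association'")
  }
  out
}

#' Write / read a cohort table as CSV
#'
#' The leading columns follow the fixed schema
#' `subject_id,group,age,sex,bmi,hba1c,duration,psqi,ess,moca,osa`; any
#' additional columns (ALPS targets, diffusivity targets) are appended.
#'
#' @param cohort Cohort data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  lead <- c("subject_id", "group", "age", "sex", "bmi", "hba1c", "duration",
            "psqi", "ess", "moca", "osa")
  cols <- c(intersect(lead, names(cohort)), setdiff(names(cohort), lead))
  utils::write.csv(cohort[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Resolve a run configuration
#'
#' Merges a YAML file (or list) with the package defaults; the resolved
#' configuration round-trips losslessly through YAML.
#'
#' @param config Path to a YAML file, a list of overrides, or `NULL` for the
#'   defaults.
#' @return A named list of run parameters.
#' @export
run_config <- function(config = NULL) {
  defaults <- list(
    seed = 42L,
    n_t2dm = 78L, n_control = 106L,
    grid_shape = c(40L, 40L, 10L),
    S0 = 1000, noise_sigma = 1000 / 30,
    noise_model = "rician",
    k = 3, weighted = FALSE,
    covars = c("age", "sex", "bmi"),
    extended = FALSE,
    bonferroni_m = 13L,
    welch = FALSE,
    keep_maps = FALSE
  )
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    yaml::read_yaml(config)
  } else {
    config
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, user)
}

#' Run the full simulate-fit-extract-compare pipeline
#'
#' For each synthetic subject: build the phantom realising that subject's
#' diffusivity targets, simulate the DWI acquisition (31 volumes: one b = 0
#' plus 30 directions at b = 800 s/mm^2), estimate the background noise,
#' mask, fit tensors, extract ROI means and the ALPS index; then run the
#' group statistics on the recovered values. Identical seeds give identical
#' outputs. Per-subject simulation seeds are derived as `seed + subject
#' index`. Errors are re-raised with the failing pipeline stage named.
#'
#' @param config Configuration as for [run_config()].
#' @param out_dir Optional directory; when given, the cohort CSV, per-subject
#'   ALPS CSV, report CSV/JSON and resolved config YAML are written there
#'   (existing files are an error — partial outputs are never overwritten
#'   silently).
#' @return List with `cohort` (including the recovered `alps` column),
#'   `alps` (per-subject results data frame), `report` (an `alps_report`)
#'   and `config`.
#' @export
end_to_end <- function(config = NULL, out_dir = NULL) {
  cfg <- run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  sim <- stage("simulate", {
    spec <- cohort_spec(n_t2dm = cfg$n_t2dm, n_control = cfg$n_control,
                        seed = cfg$seed)
    sample_cohort(spec, seed = cfg$seed, phantoms = TRUE,
                  grid_shape = cfg$grid_shape)
  })

  alps_rows <- stage("fit/alps", {
    scheme <- make_gradient_scheme(30, 800, n_b0 = 1, seed = cfg$seed)
    rows <- lapply(seq_len(nrow(sim$cohort)), function(i) {
      pspec <- sim$phantom_specs[[i]]
      pspec$S0 <- cfg$S0
      pspec$noise_sigma <- cfg$noise_sigma
      phant <- build_phantom(pspec)
      dwi <- simulate_dwi(phant, scheme,
                          noise_sigma = cfg$noise_sigma,
                          noise_model = cfg$noise_model,
                          seed = cfg$seed + i,
                          voxel_size = c(1.7, 1.7, 1.7))
      res <- subject_alps(dwi, phant$rois, k = cfg$k,
                          weighted = cfg$weighted,
                          subject_id = sim$cohort$subject_id[i])
      c(list(subject_id = res$subject_id, alps = res$alps_index),
        as.list(res$roi_diffusivities * 1e3))
    })
    do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  })

  report <- stage("stats", {
    run_table1_table2(
      sim$cohort, alps = alps_rows,
      covars = cfg$covars, extended = cfg$extended,
      bonferroni_m = cfg$bonferroni_m, welch = cfg$welch
    )
  })

  cohort <- sim$cohort
  cohort$alps <- alps_rows$alps[match(cohort$subject_id, alps_rows$subject_id)]

  if (!is.null(out_dir)) {
    stage("write", {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      paths <- file.path(out_dir, c("cohort.csv", "alps.csv",
                                    "report.csv", "report.json",
                                    "config.yaml"))
      exists <- file.exists(paths)
      if (any(exists)) {
        stopf("refusing to overwrite existing output: %s",
              paste(paths[exists], collapse = ", "))
      }
      write_cohort_csv(cohort, paths[1])
      utils::write.csv(alps_rows, paths[2], row.names = FALSE)
      write_report(report, paths[3], format = "csv")
      write_report(report, paths[4], format = "json")
      yaml::write_yaml(cfg, paths[5])
    })
  }

  list(cohort = cohort, alps = alps_rows, report = report, config = cfg)
}
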