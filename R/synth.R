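#' Cohort specification for the synthetic FDC generator
#'
#' Describes a normative control cohort (plus optional patients) with
#' scanner batch structure, matching the study design the package targets:
#' ~90 healthy controls scanned across two sites, with additive and
#' multiplicative site effects on FDC, Gaussian between-subject variation,
#' independent per-fixel noise, and an optional linear age effect.
#'
#' The site effect acts on the deviation from the per-fixel baseline:
#' a subject in batch `b` with pre-site value `x` at a fixel with baseline
#' `mu0_f` is observed as `mu0_f + batch_shift[b] + batch_scale[b] * (x - mu0_f)`.
#'
#' @param n_controls Number of control subjects (default 90).
#' @param n_patients Number of patient subjects (lesions are implanted
#'   separately with [implant_lesion()]).
#' @param batch_labels Site names; subjects are split as evenly as possible
#'   across them in order.
#' @param batch_shift Additive site effect per site, FDC units.
#' @param batch_scale Multiplicative site noise scale per site (> 0).
#' @param mu0 Baseline mean FDC; per-fixel baselines are drawn lognormal
#'   around `mu0` (FDC is non-negative by definition) with spread
#'   `mu0_spread` (log-sd).
#' @param mu0_spread Log-sd of the per-fixel baseline draw (0 = constant).
#' @param cv Between-subject coefficient of variation of the shared subject
#'   effect (>= 0).
#' @param fixel_noise SD of independent per-fixel noise, FDC units.
#' @param age_range Uniform age range in years.
#' @param age_slope FDC change per year of age (default 0).
#' @param seed RNG seed; identical seeds give bit-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 90, n_patients = 0,
                        batch_labels = c("siteA", "siteB"),
                        batch_shift = c(0, 0), batch_scale = c(1, 1),
                        mu0 = 0.5, mu0_spread = 0.1,
                        cv = 0.1, fixel_noise = 0.025,
                        age_range = c(18, 64), age_slope = 0,
                        seed = 1L) {
  if (cv < 0) abort_fixelnorm("cv must be >= 0", "fixelnorm_parameter_error")
  if (any(batch_scale <= 0)) {
    abort_fixelnorm("batch_scale must be > 0", "fixelnorm_parameter_error")
  }
  if (length(batch_shift) != length(batch_labels) ||
      length(batch_scale) != length(batch_labels)) {
    abort_fixelnorm("batch_shift/batch_scale must match batch_labels",
                    "fixelnorm_parameter_error")
  }
  structure(list(
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    batch_labels = batch_labels, batch_shift = batch_shift,
    batch_scale = batch_scale, mu0 = mu0, mu0_spread = mu0_spread,
    cv = cv, fixel_noise = fixel_noise, age_range = age_range,
    age_slope = age_slope, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Lesion specification
#'
#' A focal FDC reduction inside one tract mask, emulating the focal
#' white-matter abnormalities the normative pipeline is designed to
#' detect.
#'
#' @param tract_name Name of the target tract mask.
#' @param reduction Fractional FDC decrease in lesioned fixels, in (0, 1].
#' @param extent Fraction of the tract's fixels affected, in (0, 1].
#' @param seed RNG seed for selecting affected fixels.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(tract_name, reduction, extent = 1, seed = 1L) {
  if (!(reduction >= 0 && reduction <= 1)) {
    abort_fixelnorm("reduction must be in [0, 1]", "fixelnorm_parameter_error")
  }
  if (!(extent > 0 && extent <= 1)) {
    abort_fixelnorm("extent must be in (0, 1]", "fixelnorm_parameter_error")
  }
  structure(list(tract_name = tract_name, reduction = reduction,
                 extent = extent, seed = as.integer(seed)),
            class = "lesion_spec")
}

#' Generate a random valid fixel template
#'
#' Fixel counts are drawn per voxel (a voxel is occupied with probability
#' `fill`, and then holds 1..`max_fixels_per_voxel` fixels uniformly);
#' directions are uniform on the unit sphere; offsets are assigned
#' contiguously in voxel storage order.
#'
#' @param grid_dims Three positive integers (intended small, e.g. <= 20^3).
#' @param max_fixels_per_voxel Maximum fixels in one voxel (>= 1).
#' @param fill Fraction of occupied voxels, in (0, 1].
#' @param seed RNG seed.
#' @return A [fixel_template()] that passes [validate_template()].
#' @export
make_template <- function(grid_dims = c(10, 10, 10),
                          max_fixels_per_voxel = 3, fill = 0.5, seed = 1L) {
  if (!(fill > 0 && fill <= 1)) {
    abort_fixelnorm("fill must be in (0, 1]", "fixelnorm_parameter_error")
  }
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1),
            max_fixels_per_voxel >= 1)
  with_seed(seed, {
    n_vox <- prod(grid_dims)
    occupied <- runif(n_vox) <= fill
    counts <- integer(n_vox)
    counts[occupied] <- sample.int(max_fixels_per_voxel, sum(occupied),
                                   replace = TRUE)
    n_fixels <- sum(counts)
    offsets <- integer(n_vox)
    offsets[counts > 0] <- cumsum(counts[counts > 0]) - counts[counts > 0]
    dirs <- matrix(rnorm(n_fixels * 3), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    fixel_template(array(counts, grid_dims), array(offsets, grid_dims),
                   dirs)
  })
}

#' Standard tract set
#'
#' The 23 tracts-of-interest used throughout the package: 11 bilateral
#' pairs (arcuate fasciculus, cingulum, corticospinal tract, fornix,
#' inferior fronto-occipital and inferior longitudinal fasciculi, superior
#' cerebellar peduncle, the three superior longitudinal fasciculus
#' segments, uncinate fasciculus) plus the corpus callosum as the single
#' midline tract.
#'
#' @return Tibble with columns `name`, `bundle`, `hemisphere`.
#' @export
standard_tracts <- function() {
  bundles <- c("AF", "CG", "CST", "FX", "IFOF", "ILF", "SCP",
               "SLF_I", "SLF_II", "SLF_III", "UF")
  dplyr::bind_rows(
    tibble(name = "CC", bundle = "CC", hemisphere = "midline"),
    tidyr::expand_grid(bundle = bundles, hemisphere = c("L", "R")) |>
      dplyr::mutate(name = paste0(.data$bundle, "_",
                                  ifelse(.data$hemisphere == "L",
                                         "left", "right"))) |>
      dplyr::select("name", "bundle", "hemisphere")
  )
}

#' Generate disjoint synthetic tract masks
#'
#' Partitions a random subset of the template's fixels into named tract
#' masks. Left/right members of a bilateral pair receive equally many
#' fixels; masks are pairwise disjoint.
#'
#' @param template A [fixel_template()].
#' @param tracts Tibble as returned by [standard_tracts()] (columns `name`,
#'   `hemisphere`), or a character vector of names with hemispheres
#'   inferred from `_left`/`_right` suffixes.
#' @param seed RNG seed.
#' @return Named list of [tract_mask()] objects.
#' @export
make_tract_masks <- function(template, tracts = standard_tracts(),
                             seed = 1L) {
  if (is.character(tracts)) {
    tracts <- tibble(
      name = tracts,
      hemisphere = dplyr::case_when(
        grepl("_left$", tracts) ~ "L",
        grepl("_right$", tracts) ~ "R",
        TRUE ~ "midline"))
  }
  n_masks <- nrow(tracts)
  per_mask <- template$n_fixels %/% (n_masks + 1L)  # leave some unassigned
  if (per_mask < 1L) {
    abort_fixelnorm(
      sprintf("template has %d fixels; too small for %d masks",
              template$n_fixels, n_masks),
      "fixelnorm_capacity_error")
  }
  with_seed(seed, {
    pool <- sample.int(template$n_fixels) - 1L  # 0-based fixel indices
    out <- list()
    at <- 1L
    for (i in seq_len(n_masks)) {
      idx <- sort(pool[at:(at + per_mask - 1L)])
      at <- at + per_mask
      out[[tracts$name[i]]] <- tract_mask(tracts$name[i],
                                          tracts$hemisphere[i], idx,
                                          template)
    }
    out
  })
}

#' Simulate a control + patient cohort of per-fixel FDC fields
#'
#' Each subject's fixel value is
#' `mu0_f + age_slope * age_s + u_s + e`, with `u_s ~ N(0, (cv * mu0)^2)` a
#' shared subject effect and `e ~ N(0, fixel_noise^2)` independent fixel
#' noise, after which the site effect
#' `mu0_f + batch_shift[b] + batch_scale[b] * (x - mu0_f)` is applied and
#' values are truncated at zero (FDC is non-negative). Patients are drawn
#' from the same generative model; focal pathology is added afterwards
#' with [implant_lesion()].
#'
#' @param template A [fixel_template()].
#' @param spec A [cohort_spec()].
#' @return List with `fdc` (named list of [fixel_scalar()], one per
#'   subject) and `metadata` (tibble: `id`, `group`, `batch`, `age`,
#'   `sex`).
#' @export
simulate_cohort <- function(template, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_controls + spec$n_patients
  with_seed(spec$seed, {
    ids <- c(sprintf("C%03d", seq_len(spec$n_controls)),
             if (spec$n_patients > 0) sprintf("P%03d", seq_len(spec$n_patients)))
    group <- rep(c("control", "patient"),
                 c(spec$n_controls, spec$n_patients))
    batch_idx <- rep_len(seq_along(spec$batch_labels), n)
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex <- sample(c("F", "M"), n, replace = TRUE)

    nf <- template$n_fixels
    mu0_f <- if (spec$mu0_spread > 0) {
      spec$mu0 * exp(rnorm(nf, -spec$mu0_spread^2 / 2, spec$mu0_spread))
    } else rep(spec$mu0, nf)

    u <- rnorm(n, 0, spec$cv * spec$mu0)
    fdc <- vector("list", n)
    names(fdc) <- ids
    for (s in seq_len(n)) {
      x <- mu0_f + spec$age_slope * age[s] + u[s] +
        rnorm(nf, 0, spec$fixel_noise)
      b <- batch_idx[s]
      x <- mu0_f + spec$batch_shift[b] + spec$batch_scale[b] * (x - mu0_f)
      fdc[[s]] <- fixel_scalar(pmax(x, 0), template)
    }
    list(
      fdc = fdc,
      metadata = tibble(id = ids, group = group,
                        batch = spec$batch_labels[batch_idx],
                        age = age, sex = sex)
    )
  })
}

#' Implant a focal lesion into a per-fixel FDC field
#'
#' Multiplies an `extent`-fraction of the mask's fixels by
#' `1 - reduction`; all fixels outside the selection are untouched.
#'
#' @param fdc A [fixel_scalar()] FDC field.
#' @param mask A [tract_mask()] on the same template.
#' @param lesion A [lesion_spec()].
#' @return A new [fixel_scalar()] with the lesion applied.
#' @export
implant_lesion <- function(fdc, mask, lesion) {
  stopifnot(inherits(fdc, "fixel_scalar"), inherits(mask, "tract_mask"),
            inherits(lesion, "lesion_spec"))
  if (length(mask$fixel_indices) == 0L) {
    abort_fixelnorm("cannot implant a lesion into an empty mask",
                    "fixelnorm_parameter_error")
  }
  if (!identical(fdc$template_id, mask$template_id)) {
    abort_fixelnorm("mask and FDC field are bound to different templates",
                    "fixelnorm_binding_error")
  }
  n_mask <- length(mask$fixel_indices)
  n_hit <- max(1L, round(lesion$extent * n_mask))
  hit <- with_seed(lesion$seed, {
    sort(sample(mask$fixel_indices, n_hit))
  })
  out <- fdc
  out$values[hit + 1L] <- out$values[hit + 1L] * (1 - lesion$reduction)
  out
}

#' Write a simulated cohort to disk
#'
#' Emits a complete fixel directory (index, directions, one FDC data file
#' per subject), the tract masks as binary per-fixel data files in a
#' `masks/` subdirectory, `subjects.csv`, and a YAML manifest of the
#' generating parameters.
#'
#' @param template A [fixel_template()].
#' @param cohort Result of [simulate_cohort()].
#' @param masks Named list of [tract_mask()] (optional).
#' @param dir Output directory.
#' @param spec The generating [cohort_spec()], recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(template, cohort, masks = NULL, dir,
                         spec = NULL) {
  write_fixel_directory(template, cohort$fdc, dir)
  if (!is.null(masks)) {
    mask_scalars <- lapply(masks, function(m) {
      v <- numeric(template$n_fixels)
      v[m$fixel_indices + 1L] <- 1
      fixel_scalar(v, template)
    })
    write_fixel_directory(template, mask_scalars, file.path(dir, "masks"))
  }
  write.csv(cohort$metadata, file.path(dir, "subjects.csv"),
            row.names = FALSE)
  if (!is.null(spec)) {
    yaml::write_yaml(unclass(spec), file.path(dir, "manifest.yaml"))
  }
  invisible(dir)
}
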