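#' Pipeline configuration
#'
#' Assembles and validates the configuration for an end-to-end run:
#' synthetic cohort generation, per-subject ReHo, bilateral regional
#' tables, covariate-adjusted effect-size maps, spin tests against a
#' template map, and RVI scoring. Every random stage draws from its own
#' stream derived from the master seed via [stage_seed].
#'
#' Case deficits are planted in the BOLD simulation as a per-region
#' drop in local temporal coherence: subject i's coherence in region j
#' is `base_coherence + dx_i * g_i * coherence_deficit_j` (clamped to
#' \[0, 0.95\]), where `g_i` is a per-case pattern-strength factor
#' drawn Uniform(0.5, 1.5); case severity ratings are a noisy linear
#' function of `g_i` at the configured `severity_link`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param grid_shape,n_region_pairs,n_timepoints Synthetic volume shape,
#'   bilateral pair count and time points.
#' @param n_cases,n_controls Group sizes.
#' @param base_coherence Control-level regional coherence in \[0, 1).
#' @param coherence_deficit Per bilateral-pair additive coherence change
#'   for cases (scalar recycled; negative = deficit). Default: a graded
#'   pattern from -0.35 to -0.05 across pairs.
#' @param noise_sd BOLD noise scale.
#' @param min_neighbors ReHo neighborhood floor.
#' @param adjustment Covariate adjustment mode, see [residualize].
#' @param alpha Significance level for regional flags.
#' @param n_perm Spin permutations.
#' @param severity_link Target severity-pattern correlation.
#' @param template_path Optional template TSV (columns `region`, `d`);
#'   if `NULL` the simulate stage writes the planted deficit pattern as
#'   the template.
#' @param write_reho_maps Keep per-subject ReHo NIfTI volumes.
#' @param stages Character subset of
#'   `c("simulate", "reho", "esmap", "spin", "rvi")`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            grid_shape = c(24L, 24L, 24L),
                            n_region_pairs = 8L, n_timepoints = 60L,
                            n_cases = 30L, n_controls = 30L,
                            base_coherence = 0.5, coherence_deficit = NULL,
                            noise_sd = 1, min_neighbors = 2L,
                            adjustment = "pooled", alpha = 0.05,
                            n_perm = 999L, severity_link = 0.4,
                            template_path = NULL, write_reho_maps = FALSE,
                            stages = c("simulate", "reho", "esmap",
                                       "spin", "rvi")) {
  # default: a graded deficit pattern (strongest to mildest across pairs),
  # so the planted map has spatial structure for the spin and RVI stages
  cd <- as.numeric(coherence_deficit %||%
                     seq(-0.35, -0.05, length.out = n_region_pairs))
  if (length(cd) == 1L) cd <- rep(cd, n_region_pairs)
  if (length(cd) != n_region_pairs)
    stop("coherence_deficit must be scalar or one value per region pair")
  stages <- match.arg(stages, several.ok = TRUE)
  if (base_coherence < 0 || base_coherence >= 1)
    stop("base_coherence must lie in [0, 1)")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 grid_shape = as.integer(grid_shape),
                 n_region_pairs = as.integer(n_region_pairs),
                 n_timepoints = as.integer(n_timepoints),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 base_coherence = base_coherence, coherence_deficit = cd,
                 noise_sd = noise_sd, min_neighbors = as.integer(min_neighbors),
                 adjustment = adjustment, alpha = alpha,
                 n_perm = as.integer(n_perm), severity_link = severity_link,
                 template_path = template_path,
                 write_reho_maps = isTRUE(write_reho_maps),
                 stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

pipeline_paths <- function(cfg) {
  o <- cfg$out_dir
  list(atlas = file.path(o, "atlas.nii.gz"),
       regions = file.path(o, "regions.tsv"),
       subjects = file.path(o, "subjects.tsv"),
       bold_dir = file.path(o, "bold"),
       template = cfg$template_path %||% file.path(o, "template.tsv"),
       regional_uni = file.path(o, "regional_reho_unilateral.tsv"),
       regional = file.path(o, "regional_reho.tsv"),
       esmap = file.path(o, "esmap.tsv"),
       esmap_summary = file.path(o, "esmap_summary.json"),
       spin = file.path(o, "spin.json"),
       rvi = file.path(o, "rvi.tsv"),
       rvi_summary = file.path(o, "rvi_summary.json"),
       manifest = file.path(o, "manifest.json"))
}

need_file <- function(path, stage, producer) {
  if (!file.exists(path))
    stop("dependency error: stage '", stage, "' needs ", path,
         " (produced by stage '", producer, "')")
  path
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic biomarker pipeline
#'
#' Executes the enabled stages in dependency order. Each stage reads
#' only files written by earlier stages (never in-memory state), so
#' stages can be re-run individually; rerunning the same configuration
#' reproduces byte-identical tables. A run manifest (configuration,
#' seed, package version, output digests) is written alongside the
#' outputs.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- pipeline_paths(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in c("simulate", "reho", "esmap", "spin", "rvi"))
    if (st %in% config$stages)
      switch(st,
             simulate = stage_simulate(config, p),
             reho = stage_reho(config, p),
             esmap = stage_esmap(config, p),
             spin = stage_spin(config, p),
             rvi = stage_rvi(config, p))
  outputs <- Filter(file.exists, unlist(p[names(p) != "bold_dir"]))
  manifest <- list(package = "corticalmark",
                   version = as.character(utils::packageVersion("corticalmark")),
                   seed = config$seed, stages = config$stages,
                   config = unclass(config),
                   digests = as.list(tools::md5sum(outputs)))
  write_json_file(manifest, p$manifest)
  invisible(manifest)
}

stage_simulate <- function(cfg, p) {
  s <- stage_seed(cfg$seed, "simulate")
  atlas <- make_toy_atlas(cfg$grid_shape, cfg$n_region_pairs, seed = s)
  write_atlas(atlas, p$atlas, p$regions)
  n <- cfg$n_cases + cfg$n_controls
  withr::with_seed(s, {
    dx <- c(rep(1L, cfg$n_cases), rep(0L, cfg$n_controls))
    age <- stats::runif(n, 20, 70)
    sex <- stats::rbinom(n, 1L, 0.5)
    g <- ifelse(dx == 1L, stats::runif(n, 0.5, 1.5), 0)
    sev <- rep(NA_real_, n)
    case <- which(dx == 1L)
    gs <- (g[case] - mean(g[case])) / max(stats::sd(g[case]), 1e-12)
    rho <- cfg$severity_link
    sev[case] <- 20 + 8 * (rho * gs + sqrt(max(0, 1 - rho^2)) *
                             stats::rnorm(length(case)))
  })
  subjects <- data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
                         age = age, sex = sex, dx = dx, severity = sev,
                         pattern_strength = g, stringsAsFactors = FALSE)
  utils::write.table(subjects, p$subjects, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  dir.create(p$bold_dir, showWarnings = FALSE)
  pair_of <- (atlas$regions$id + 1L) %/% 2L     # bilateral pair per region row
  for (i in seq_len(n)) {
    coh <- pmin(pmax(cfg$base_coherence +
                       dx[i] * g[i] * cfg$coherence_deficit[pair_of], 0), 0.95)
    vts <- simulate_bold(atlas, cfg$n_timepoints, coherence = coh,
                         noise_sd = cfg$noise_sd, seed = s + i)
    RNifti::writeNifti(vts$data,
                       file.path(p$bold_dir, paste0(subjects$subject_id[i], ".nii")),
                       datatype = "float")
  }
  if (is.null(cfg$template_path)) {
    # planted deficit pattern on the bilateral regions, as case - control d
    tmpl <- stats::setNames(cfg$coherence_deficit,
                            sprintf("region_%02d", seq_len(cfg$n_region_pairs)))
    write_template_tsv(tmpl, p$template)
  }
  invisible(NULL)
}

stage_reho <- function(cfg, p) {
  atlas <- read_atlas(need_file(p$atlas, "reho", "simulate"),
                      need_file(p$regions, "reho", "simulate"))
  subjects <- utils::read.delim(need_file(p$subjects, "reho", "simulate"),
                                stringsAsFactors = FALSE)
  rows <- lapply(subjects$subject_id, function(id) {
    f <- need_file(file.path(p$bold_dir, paste0(id, ".nii")), "reho", "simulate")
    dat <- as.array(RNifti::readNifti(f))
    vts <- volume_time_series(dat, mask = atlas$labels > 0L)
    rm_ <- reho_map(vts, min_neighbors = cfg$min_neighbors)
    if (cfg$write_reho_maps)
      RNifti::writeNifti(rm_$values, file.path(p$bold_dir, paste0(id, "_reho.nii")))
    extract_regional_means(rm_$values, atlas)
  })
  m <- do.call(rbind, rows)
  tab <- regional_table(subjects[c("subject_id", "age", "sex", "dx", "severity")],
                        m, measure_name = "reho")
  write_regional_tsv(tab, p$regional_uni)
  write_regional_tsv(average_hemispheres(tab), p$regional)
  invisible(NULL)
}

stage_esmap <- function(cfg, p) {
  tab <- read_regional_tsv(need_file(p$regional, "esmap", "reho"), "reho")
  adj <- residualize(tab, adjustment = cfg$adjustment)
  map <- flag_significant(cohens_d_map(adj$table), alpha = cfg$alpha)
  write_effect_map_tsv(map, p$esmap)
  sm <- summarize_map(map)
  write_json_file(list(mean_d = sm$mean_d, sd_d = sm$sd_d,
                       n_regions = sm$n_regions,
                       n_significant = sum(map$significant_bonferroni,
                                           na.rm = TRUE)),
                  p$esmap_summary)
  invisible(NULL)
}

# bilateral maps are spun on single (left) hemisphere centroids
bilateral_centroids <- function(regions, region_names) {
  left <- regions[regions$hemisphere == "L", ]
  idx <- match(canonical_region_name(region_names),
               canonical_region_name(left$name))
  if (anyNA(idx))
    stop("no left-hemisphere centroid for region(s): ",
         paste(region_names[is.na(idx)], collapse = ", "))
  as.matrix(left[idx, c("cx", "cy", "cz")])
}

stage_spin <- function(cfg, p) {
  map <- read_effect_map_tsv(need_file(p$esmap, "spin", "esmap"))
  tmpl <- read_template_tsv(need_file(p$template, "spin", "simulate"))
  regions <- utils::read.delim(need_file(p$regions, "spin", "simulate"),
                               stringsAsFactors = FALSE)
  names(regions)[names(regions) == "region"] <- "name"
  idx <- match(canonical_region_name(map$region),
               canonical_region_name(names(tmpl)))
  if (anyNA(idx))
    stop("template is missing region(s): ",
         paste(map$region[is.na(idx)], collapse = ", "))
  cent <- bilateral_centroids(regions, map$region)
  res <- spin_permutation_p(map$d, as.numeric(tmpl)[idx], cent,
                            n_perm = cfg$n_perm,
                            seed = stage_seed(cfg$seed, "spin"))
  write_json_file(list(r = res$r, n_regions = res$n_regions,
                       p_spin = res$p_spin, n_perm = res$n_perm,
                       seed = res$seed), p$spin)
  invisible(NULL)
}

stage_rvi <- function(cfg, p) {
  tab <- read_regional_tsv(need_file(p$regional, "rvi", "reho"), "reho")
  tmpl <- read_template_tsv(need_file(p$template, "rvi", "simulate"))
  adj <- residualize(tab, adjustment = cfg$adjustment)$table
  ref <- build_control_reference(adj)
  z <- zscore_subjects(adj, ref)
  scores <- rvi_scores(z, tmpl[canonical_region_name(names(tmpl)) %in%
                                 canonical_region_name(ref$region)])
  utils::write.table(scores, p$rvi, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  contrast <- rvi_group_contrast(scores$rvi, tab$subjects$dx)
  assoc <- tryCatch(rvi_symptom_association(scores$rvi, tab$subjects$severity),
                    error = function(e) NULL)
  write_json_file(list(contrast = contrast, association = assoc), p$rvi_summary)
  invisible(NULL)
}

#' Validate pipeline inputs
#'
#' Structural checks on a set of pipeline inputs: atlas label /
#' region-table agreement, centroid norms, NIfTI shape agreement
#' between BOLD and atlas, duplicate subjects, covariate completeness
#' and dx/sex coding. Returns a machine-readable issue table; an empty
#' table means the inputs are clean.
#'
#' @param atlas_path,regions_path Atlas NIfTI and region TSV paths.
#' @param table_path Optional regional-table TSV.
#' @param bold_paths Optional character vector of 4-D NIfTI paths.
#' @return Data frame with columns `severity` (`"fatal"`/`"warning"`)
#'   and `issue`.
#' @export
validate_inputs <- function(atlas_path, regions_path, table_path = NULL,
                            bold_paths = NULL) {
  issues <- data.frame(severity = character(), issue = character(),
                       stringsAsFactors = FALSE)
  add <- function(sev, msg) {
    issues[nrow(issues) + 1L, ] <<- list(sev, msg)
  }
  atlas <- NULL
  lab_img <- tryCatch(RNifti::readNifti(atlas_path), error = function(e) NULL)
  reg <- tryCatch(utils::read.delim(regions_path, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(lab_img)) add("fatal", paste("cannot read atlas:", atlas_path))
  if (is.null(reg)) add("fatal", paste("cannot read region table:", regions_path))
  if (!is.null(lab_img) && !is.null(reg)) {
    labels <- as.array(lab_img)
    present <- sort(unique(as.integer(labels[labels > 0])))
    only_grid <- setdiff(present, reg$id)
    only_tab <- setdiff(reg$id, present)
    if (length(only_grid))
      add("fatal", paste("atlas label(s) missing from region table:",
                         paste(only_grid, collapse = ",")))
    if (length(only_tab))
      add("fatal", paste("region table id(s) absent from atlas grid:",
                         paste(only_tab, collapse = ",")))
    if (all(c("cx", "cy", "cz") %in% names(reg))) {
      nrm <- sqrt(reg$cx^2 + reg$cy^2 + reg$cz^2)
      if (any(abs(nrm - 1) > 1e-6))
        add("fatal", "region centroids are not unit-norm")
    } else add("fatal", "region table lacks centroid columns cx, cy, cz")
    for (f in bold_paths) {
      di <- tryCatch(dim(RNifti::readNifti(f)), error = function(e) NULL)
      if (is.null(di)) { add("fatal", paste("cannot read BOLD:", f)); next }
      if (length(di) != 4L)
        add("fatal", paste0(f, " is not 4-D"))
      else if (!all(di[1:3] == dim(labels)))
        add("fatal", paste0(f, " spatial shape disagrees with atlas"))
    }
  }
  if (!is.null(table_path)) {
    df <- tryCatch(utils::read.delim(table_path, stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) add("fatal", paste("cannot read table:", table_path))
    else {
      if (anyDuplicated(df$subject_id))
        add("fatal", paste("duplicated subject_id:",
                           paste(unique(df$subject_id[duplicated(df$subject_id)]),
                                 collapse = ",")))
      for (cv in c("age", "sex", "dx"))
        if (!cv %in% names(df)) add("fatal", paste("missing covariate:", cv))
        else if (anyNA(df[[cv]])) add("fatal", paste("missing values in", cv))
      if ("dx" %in% names(df) && !all(stats::na.omit(df$dx) %in% c(0, 1)))
        add("fatal", "dx must be coded 0/1")
    }
  }
  issues
}
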