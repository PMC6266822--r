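#' Specify a planted co-expression module
#'
#' A module is a set of genes driven by one latent trajectory per individual.
#' Member genes load on the trajectory with sign +1 or -1; a
#' `negative_fraction` of members are mirrored (sign -1), producing the
#' negative correlations the network stage must recover.
#'
#' @param name Module name.
#' @param n_genes Number of member genes (>= 2).
#' @param groups Group labels in which the module is active.
#' @param negative_fraction Fraction of members with mirrored sign.
#' @param loading Signal amplitude in log2 units (> 0).
#' @param trajectory_shift Group-level mean log2 change of the latent
#'   trajectory between time points 1 and 2 (0 at later steps).
#' @return A `module_spec` list.
#' @export
module_spec <- function(name, n_genes, groups, negative_fraction = 0.25,
                        loading = 1.0, trajectory_shift = -1.0) {
  if (n_genes < 2) stop("a module needs at least 2 genes")
  if (!length(groups)) stop("a module must be active in at least one group")
  if (negative_fraction < 0 || negative_fraction > 1)
    stop("negative_fraction must lie in [0, 1]")
  if (loading <= 0) stop("loading must be > 0")
  structure(list(name = name, n_genes = as.integer(n_genes),
                 groups = as.character(groups),
                 negative_fraction = negative_fraction,
                 loading = loading, trajectory_shift = trajectory_shift),
            class = "module_spec")
}

#' Specify a synthetic two-group time-series study
#'
#' @param groups Named integer vector: individuals per group, e.g.
#'   `c(LCD = 12, VLCD = 12)`.
#' @param n_timepoints Time points per individual (>= 3).
#' @param modules List of [module_spec()]s.
#' @param n_background_genes Genes at the noise floor in all samples.
#' @param n_y_genes Y-chromosome genes: baseline in males, noise floor in
#'   females.
#' @param female_fraction Fraction of individuals that are female (at least
#'   one female overall is guaranteed).
#' @param noise_sd Measurement noise SD in log2 units (> 0).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 level
#'   distribution for expressed genes.
#' @param background_level Noise-floor log2 level (below baseline).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `study_spec` list.
#' @export
study_spec <- function(groups = c(LCD = 12L, VLCD = 12L),
                       n_timepoints = 3L,
                       modules = default_modules(names(groups)),
                       n_background_genes = 200L,
                       n_y_genes = 20L,
                       female_fraction = 0.5,
                       noise_sd = 0.25,
                       baseline_mean = 7,
                       baseline_sd = 0.5,
                       background_level = 4,
                       seed = 42L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("`groups` must be a named vector of individuals per group")
  if (any(groups < 1)) stop("zero individuals in a declared group")
  if (n_timepoints < 3) stop("n_timepoints must be >= 3")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (n_background_genes < 0 || n_y_genes < 0) stop("counts must be >= 0")
  if (female_fraction < 0 || female_fraction > 1)
    stop("female_fraction must lie in [0, 1]")
  if (n_y_genes > 0 && female_fraction == 0 && sum(groups) > 0)
    stop("Y genes require at least one female individual")
  for (m in modules) {
    bad <- setdiff(m$groups, names(groups))
    if (length(bad))
      stop("module '", m$name, "' active in unknown group(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(groups = groups, n_timepoints = as.integer(n_timepoints),
                 modules = modules,
                 n_background_genes = as.integer(n_background_genes),
                 n_y_genes = as.integer(n_y_genes),
                 female_fraction = female_fraction, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "study_spec")
}

#' Default planted-module layout for a two-group study
#'
#' Five modules of 8 genes: three active in both groups, one unique to each
#' group; a quarter of members mirrored, loading 1 log2 unit, group-level
#' shift of -1 log2 unit during the first interval.
#'
#' @param group_names Character vector of exactly two group labels.
#' @return List of [module_spec()]s.
#' @export
default_modules <- function(group_names = c("LCD", "VLCD")) {
  if (length(group_names) != 2)
    stop("default module layout expects exactly two groups")
  c(lapply(1:3, function(i)
      module_spec(paste0("M", i), 8, group_names)),
    list(module_spec("M4", 8, group_names[1]),
         module_spec("M5", 8, group_names[2])))
}

#' Generate a synthetic study with planted modules and ground truth
#'
#' Per individual and active module a latent trajectory is drawn:
#' `z(1) = 0`, `z(t+1) = z(t) + shift_t + N(0, 1)`, with the group-level
#' `trajectory_shift` applied between time points 1 and 2 and 0 afterwards.
#' A member gene's value is `baseline_g + sign_g * loading * z_i(t) +
#' N(0, noise_sd)`. Background genes sit at `background_level +
#' N(0, noise_sd)` in all samples; Y-chromosome genes behave like expressed
#' genes in males and like background in females. Sexes are assigned
#' deterministically (the first `round(female_fraction * n)` individuals of
#' each group are female; at least one female overall). One RNG stream
#' seeded from `spec$seed` is consumed in a fixed order (module-gene
#' baselines, Y baselines, latent trajectories by group/module/individual,
#' then one noise draw per matrix cell), so output is reproducible.
#'
#' @param spec A [study_spec()].
#' @return List with class `synthetic_study`: `expr` (an
#'   [expression_study()]), `chrom` (gene -> chromosome map), and `truth`
#'   (a `study_truth`: per-gene role/sign table, planted within-module edge
#'   set per group, and the shared-edge set of modules active in all
#'   groups).
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  set.seed(spec$seed)
  T <- spec$n_timepoints
  grp_names <- names(spec$groups)

  # individuals and samples
  ind_tab <- do.call(rbind, lapply(grp_names, function(g) {
    n <- spec$groups[[g]]
    n_f <- round(spec$female_fraction * n)
    data.frame(individual_id = sprintf("%s_I%02d", g, seq_len(n)),
               group = g,
               sex = rep(c("female", "male"), c(n_f, n - n_f)),
               stringsAsFactors = FALSE)
  }))
  if (spec$n_y_genes > 0 && !any(ind_tab$sex == "female"))
    ind_tab$sex[1] <- "female"   # at least one female guaranteed
  samples <- do.call(rbind, lapply(seq_len(nrow(ind_tab)), function(i) {
    data.frame(sample_id = sprintf("%s_T%d", ind_tab$individual_id[i],
                                   seq_len(T)),
               individual_id = ind_tab$individual_id[i],
               group = ind_tab$group[i], timepoint = seq_len(T),
               sex = ind_tab$sex[i], stringsAsFactors = FALSE)
  }))

  # gene roster: module genes, then background, then Y
  mod_genes <- list(); gene_role <- character(); gene_sign <- integer()
  for (m in spec$modules) {
    ids <- sprintf("%s_G%02d", m$name, seq_len(m$n_genes))
    sgn <- rep(1L, m$n_genes)
    n_neg <- floor(m$negative_fraction * m$n_genes)
    if (n_neg > 0) sgn[seq_len(n_neg)] <- -1L
    mod_genes[[m$name]] <- ids
    gene_role <- c(gene_role, stats::setNames(rep(m$name, m$n_genes), ids))
    gene_sign <- c(gene_sign, stats::setNames(sgn, ids))
  }
  bg_ids <- if (spec$n_background_genes)
    sprintf("BG_%04d", seq_len(spec$n_background_genes)) else character()
  y_ids <- if (spec$n_y_genes)
    sprintf("YG_%02d", seq_len(spec$n_y_genes)) else character()
  gene_role <- c(gene_role,
                 stats::setNames(rep("background", length(bg_ids)), bg_ids),
                 stats::setNames(rep("Y", length(y_ids)), y_ids))
  gene_sign <- c(gene_sign,
                 stats::setNames(rep(1L, length(bg_ids) + length(y_ids)),
                                 c(bg_ids, y_ids)))
  all_genes <- names(gene_role)

  # baselines (RNG order: module genes, then Y genes)
  baseline <- stats::setNames(rep(spec$background_level, length(all_genes)),
                              all_genes)
  n_mod_genes <- length(unlist(mod_genes))
  if (n_mod_genes)
    baseline[unlist(mod_genes)] <-
      stats::rnorm(n_mod_genes, spec$baseline_mean, spec$baseline_sd)
  if (length(y_ids))
    baseline_y <- stats::setNames(
      stats::rnorm(length(y_ids), spec$baseline_mean, spec$baseline_sd),
      y_ids)

  # latent trajectories: per group, per module, per individual
  vals <- matrix(0, nrow = length(all_genes), ncol = nrow(samples),
                 dimnames = list(all_genes, samples$sample_id))
  vals[] <- rep(baseline, times = nrow(samples))
  shift_vec <- function(m) c(m$trajectory_shift, rep(0, T - 2))
  for (g in grp_names) {
    inds <- ind_tab$individual_id[ind_tab$group == g]
    for (m in spec$modules) {
      if (!(g %in% m$groups)) next
      for (ind in inds) {
        steps <- shift_vec(m) + stats::rnorm(T - 1)
        z <- c(0, cumsum(steps))
        cols <- sprintf("%s_T%d", ind, seq_len(T))
        ids <- mod_genes[[m$name]]
        vals[ids, cols] <- vals[ids, cols] +
          outer(gene_sign[ids] * m$loading, z)
      }
    }
  }
  # Y genes: baseline in males, background level in females
  if (length(y_ids)) {
    male_cols <- samples$sample_id[samples$sex == "male"]
    if (length(male_cols))
      vals[y_ids, male_cols] <- baseline_y[y_ids]
  }
  # measurement noise, one draw per cell in column-major order
  vals <- vals + matrix(stats::rnorm(length(vals), 0, spec$noise_sd),
                        nrow = nrow(vals))

  expr <- expression_study(vals, samples)
  chrom <- stats::setNames(
    c(rep_len(as.character(1:22), n_mod_genes + length(bg_ids)),
      rep("Y", length(y_ids))),
    c(unlist(mod_genes), bg_ids, y_ids))

  planted <- lapply(grp_names, function(g) {
    act <- Filter(function(m) g %in% m$groups, spec$modules)
    do.call(rbind, c(list(empty_edge_df()),
                     lapply(act, function(m) pair_df(mod_genes[[m$name]]))))
  })
  names(planted) <- grp_names
  shared_mods <- Filter(function(m) all(grp_names %in% m$groups),
                        spec$modules)
  shared <- do.call(rbind, c(list(empty_edge_df()),
                             lapply(shared_mods,
                                    function(m) pair_df(mod_genes[[m$name]]))))
  truth <- structure(
    list(genes = data.frame(gene_id = all_genes, role = unname(gene_role),
                            sign = unname(gene_sign),
                            stringsAsFactors = FALSE),
         planted = planted, shared = shared),
    class = "study_truth")
  structure(list(expr = expr, chrom = chrom, truth = truth, spec = spec),
            class = "synthetic_study")
}

empty_edge_df <- function()
  data.frame(gene_a = character(), gene_b = character(),
             stringsAsFactors = FALSE)

pair_df <- function(ids) {
  if (length(ids) < 2) return(empty_edge_df())
  cmb <- utils::combn(sort(ids), 2)
  data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], stringsAsFactors = FALSE)
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study: seed", x$spec$seed, "\n")
  print(x$expr)
  cat("  modules:", paste(vapply(x$spec$modules, `[[`, "", "name"),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Recall and false-edge rate of a network against planted truth
#'
#' @param net A `coexpression_network`.
#' @param truth A `study_truth` from [generate_study()].
#' @param scope `"group"` (planted edges of the group named by the
#'   network's provenance) or `"shared"` (edges of modules active in all
#'   groups).
#' @param group Group label when `scope = "group"`; defaults to the
#'   network's provenance.
#' @return List with `recall` (planted edges recovered / planted) and
#'   `false_edge_rate` (non-planted edges / network edges; 0 for an empty
#'   network).
#' @export
truth_edge_metrics <- function(net, truth, scope = c("group", "shared"),
                               group = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(net, "coexpression_network"),
            inherits(truth, "study_truth"))
  planted <- if (scope == "shared") truth$shared else {
    if (is.null(group)) group <- net$provenance
    if (!group %in% names(truth$planted))
      stop("network provenance '", group,
           "' does not name a group in the truth")
    truth$planted[[group]]
  }
  pk <- paste(planted$gene_a, planted$gene_b)
  nk <- edge_keys(net)
  recall <- if (length(pk)) length(intersect(nk, pk)) / length(pk) else NA_real_
  fer <- if (length(nk)) length(setdiff(nk, pk)) / length(nk) else 0
  list(recall = recall, false_edge_rate = fer)
}

#' Write a synthetic study to disk
#'
#' Writes the expression TSV, sample sheet TSV, chromosome map TSV and the
#' ground truth as JSON.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("expression.tsv", "samples.tsv",
                            "chromosomes.tsv", "truth.json"))
  write_expression(study$expr, paths[1], paths[2])
  write_chromosome_map(study$chrom, paths[3])
  tr <- study$truth
  jsonlite::write_json(
    list(genes = tr$genes,
         planted = lapply(tr$planted, function(p)
           paste(p$gene_a, p$gene_b, sep = "|")),
         shared = paste(tr$shared$gene_a, tr$shared$gene_b, sep = "|")),
    paths[4], auto_unbox = TRUE)
  invisible(paths)
}
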