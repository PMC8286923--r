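#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort of subjects whose independent-component (IC) time
#' courses carry a block-correlation structure that differs between the two
#' groups. Each block shares one smooth AR(1) latent signal; a member
#' component is `coupling * latent + sqrt(1 - coupling^2) * noise`, so the
#' expected pairwise correlation within a block is roughly `coupling^2`
#' (attenuated by the measurement noise `noise_sd`).
#'
#' Defaults emulate the study conditions the pipeline targets: 57 + 47
#' subjects, per-subject component counts drawn uniformly from 20--40, and
#' 150 time points. The group contrast is carried by the within-block
#' coupling (stronger for the control-like group A, weaker for the
#' patient-like group B, mimicking dysconnectivity).
#'
#' @param n_group_a,n_group_b Number of subjects per group.
#' @param components_range Integer interval `c(min, max)`; per-subject
#'   component counts are drawn uniformly from it. Must lie within
#'   `[2, 200]`.
#' @param n_timepoints Number of time points per component (>= 8).
#' @param block_structure_a,block_structure_b Block structure per group: a
#'   list of `c(size, coupling)` pairs, recycled until all of a subject's
#'   components are covered. Couplings must lie in `[0, 1]`.
#' @param noise_sd Standard deviation of additive white measurement noise.
#' @param seed Integer seed; all cohort randomness flows from it.
#'
#' @return A list of class `"cohort_spec"`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_group_a = 57L, n_group_b = 47L,
                        components_range = c(20L, 40L),
                        n_timepoints = 150L,
                        block_structure_a = list(c(5, 0.8)),
                        block_structure_b = list(c(5, 0.45)),
                        noise_sd = 0.2, seed = 1L) {
  n_group_a <- check_count(n_group_a, "n_group_a", min = 1L)
  n_group_b <- check_count(n_group_b, "n_group_b", min = 1L)
  if (length(components_range) != 2L) abort_field("components_range", "must have length 2")
  components_range <- c(
    check_count(components_range[1L], "components_range", min = 2L),
    check_count(components_range[2L], "components_range", min = 2L)
  )
  if (components_range[2L] < components_range[1L] || components_range[2L] > 200L) {
    abort_field("components_range", "must be an increasing interval within [2, 200]")
  }
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 8L)
  check_blocks <- function(bs, field) {
    if (!is.list(bs) || length(bs) == 0L) abort_field(field, "must be a nonempty list of c(size, coupling)")
    for (b in bs) {
      if (length(b) != 2L || !is.numeric(b)) abort_field(field, "each element must be c(size, coupling)")
      if (b[1L] < 1 || b[1L] != as.integer(b[1L])) abort_field(field, "block size must be a positive integer")
      if (b[2L] < 0 || b[2L] > 1) abort_field(field, "coupling must lie in [0, 1]")
    }
    bs
  }
  structure(list(
    n_group_a = n_group_a, n_group_b = n_group_b,
    components_range = components_range, n_timepoints = n_timepoints,
    block_structure_a = check_blocks(block_structure_a, "block_structure_a"),
    block_structure_b = check_blocks(block_structure_b, "block_structure_b"),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "cohort_spec")
}

# One AR(1) latent signal, unit marginal variance, phi fixed at 0.8: smooth
# enough to look signal-like at T = 150 yet stationary.
ar1_latent <- function(n, phi = 0.8) {
  as.numeric(stats::arima.sim(list(ar = phi), n = n, sd = sqrt(1 - phi^2)))
}

generate_subject_timecourses <- function(m, n_timepoints, blocks, noise_sd) {
  sizes <- vapply(blocks, `[`, numeric(1), 1L)
  couplings <- vapply(blocks, `[`, numeric(1), 2L)
  # recycle block structure until m components are covered
  idx <- integer(0)
  b <- 1L
  assign_block <- integer(m)
  coupling_of <- numeric(0)
  filled <- 0L
  block_id <- 0L
  while (filled < m) {
    block_id <- block_id + 1L
    take <- min(sizes[b], m - filled)
    assign_block[(filled + 1L):(filled + take)] <- block_id
    coupling_of[block_id] <- couplings[b]
    filled <- filled + take
    b <- if (b == length(blocks)) 1L else b + 1L
  }
  A <- matrix(0, m, n_timepoints)
  for (g in seq_len(block_id)) {
    members <- which(assign_block == g)
    latent <- ar1_latent(n_timepoints)
    cpl <- coupling_of[g]
    for (i in members) {
      own <- stats::rnorm(n_timepoints)
      A[i, ] <- cpl * latent + sqrt(1 - cpl^2) * own +
        noise_sd * stats::rnorm(n_timepoints)
    }
  }
  A
}

#' Generate a synthetic two-group cohort of IC time courses
#'
#' Draws per-subject component counts uniformly from
#' `spec$components_range` and synthesizes each subject's component time
#' courses from the group's block structure (see [cohort_spec()]). All
#' randomness derives from `spec$seed` through one substream per subject, so
#' a fixed seed gives bit-identical cohorts regardless of how the result is
#' consumed.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `subject_id` (character),
#'   `group` (factor with levels `"a"`, `"b"`; `"b"` is the patient-like,
#'   positive class) and `timecourses` (list-column of components x time
#'   matrices).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_group_a = 3, n_group_b = 2, seed = 7))
#' dim(cohort$timecourses[[1]])
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  n <- spec$n_group_a + spec$n_group_b
  seeds <- split_seed(spec$seed, n)
  groups <- rep(c("a", "b"), c(spec$n_group_a, spec$n_group_b))
  rng <- spec$components_range
  rows <- purrr::map(seq_len(n), function(i) {
    g <- groups[i]
    blocks <- if (g == "a") spec$block_structure_a else spec$block_structure_b
    with_seed(seeds[i], {
      m <- if (rng[1L] == rng[2L]) rng[1L] else sample(seq(rng[1L], rng[2L]), 1L)
      A <- generate_subject_timecourses(m, spec$n_timepoints, blocks, spec$noise_sd)
      rownames(A) <- sprintf("IC%02d", seq_len(m))
      tibble::tibble(
        subject_id = sprintf("sub-%03d", i),
        group = g,
        timecourses = list(A)
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  out$group <- factor(out$group, levels = c("a", "b"))
  out
}

#' Specification of a stack of ICA realizations
#'
#' Describes `n_realizations` repeated ICA decompositions of the same data:
#' `n_reproducible` base spatial maps recur in every realization (randomly
#' permuted across component slots, randomly sign-flipped, and perturbed by
#' additive Gaussian jitter), while the remaining `n_components -
#' n_reproducible` slots are filled with fresh noise maps per realization.
#' This mimics the order/sign indeterminacy of ICA plus its run-to-run
#' variability.
#'
#' @param n_realizations Number of realizations K (>= 2).
#' @param n_components Components per realization M (>= 1).
#' @param n_reproducible How many base maps recur (0 <= value <= M).
#' @param n_voxels Spatial map length.
#' @param jitter_sd SD of the additive jitter applied to reproducible maps.
#' @param n_timepoints Optional; when supplied, a T x M mixing matrix is
#'   generated per realization (reproducible components reuse a base time
#'   course, sign-flipped consistently with the map).
#' @param seed Integer seed.
#' @return A list of class `"realization_spec"`.
#' @export
realization_spec <- function(n_realizations = 30L, n_components = 25L,
                             n_reproducible = 20L, n_voxels = 2000L,
                             jitter_sd = 0.1, n_timepoints = NULL,
                             seed = 1L) {
  n_realizations <- check_count(n_realizations, "n_realizations", min = 2L)
  n_components <- check_count(n_components, "n_components", min = 1L)
  n_reproducible <- check_count(n_reproducible, "n_reproducible", min = 0L)
  if (n_reproducible > n_components) {
    abort_field("n_reproducible", "cannot exceed n_components")
  }
  structure(list(
    n_realizations = n_realizations, n_components = n_components,
    n_reproducible = n_reproducible,
    n_voxels = check_count(n_voxels, "n_voxels", min = 2L),
    jitter_sd = check_number(jitter_sd, "jitter_sd", min = 0),
    n_timepoints = if (!is.null(n_timepoints)) check_count(n_timepoints, "n_timepoints", min = 8L),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "realization_spec")
}

#' Generate a synthetic stack of ICA realizations
#'
#' @param spec A [realization_spec()].
#' @return An object of class `"ica_stack"`: a list with `spatial_maps`
#'   (list of K matrices, M x n_voxels), `mixing` (list of K matrices T x M,
#'   or `NULL`), `K`, `M`, and a `truth` element recording, for each
#'   realization, which slot each planted base map occupies and its sign --
#'   used by recovery tests, never by the estimators.
#' @export
generate_realization_stack <- function(spec) {
  if (!inherits(spec, "realization_spec")) spec <- do.call(realization_spec, spec)
  K <- spec$n_realizations; M <- spec$n_components
  R <- spec$n_reproducible; V <- spec$n_voxels
  seeds <- split_seed(spec$seed, K + 1L)
  base_maps <- with_seed(seeds[K + 1L], {
    matrix(stats::rnorm(R * V), nrow = R, ncol = V)
  })
  base_tc <- if (!is.null(spec$n_timepoints)) {
    with_seed(seeds[K + 1L] + 1L, matrix(stats::rnorm(spec$n_timepoints * R), ncol = R))
  }
  truth_slot <- matrix(NA_integer_, nrow = K, ncol = R)
  truth_sign <- matrix(NA_real_, nrow = K, ncol = R)
  maps <- vector("list", K)
  mixing <- if (!is.null(spec$n_timepoints)) vector("list", K)
  for (k in seq_len(K)) {
    drawn <- with_seed(seeds[k], {
      S <- matrix(stats::rnorm(M * V), nrow = M, ncol = V)
      slots <- integer(0); signs <- numeric(0)
      if (R > 0L) {
        slots <- sample.int(M, R)
        signs <- sample(c(-1, 1), R, replace = TRUE)
        jit <- matrix(stats::rnorm(R * V, sd = spec$jitter_sd), nrow = R)
        S[slots, ] <- signs * (base_maps + jit)
      }
      list(S = S, slots = slots, signs = signs)
    })
    maps[[k]] <- drawn$S
    if (R > 0L) {
      truth_slot[k, ] <- drawn$slots
      truth_sign[k, ] <- drawn$signs
    }
    if (!is.null(mixing)) {
      mixing[[k]] <- with_seed(seeds[k] + 1L, {
        Tm <- matrix(stats::rnorm(spec$n_timepoints * M), ncol = M)
        if (R > 0L) {
          Tm[, truth_slot[k, ]] <- sweep(base_tc, 2L, truth_sign[k, ], `*`)
        }
        Tm
      })
    }
  }
  structure(list(
    spatial_maps = maps, mixing = mixing, K = K, M = M,
    n_voxels = V,
    truth = list(slot = truth_slot, sign = truth_sign, base_maps = base_maps)
  ), class = "ica_stack")
}
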