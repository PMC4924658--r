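#' Plan virtual case/control datasets from an integrated cohort
#'
#' Resamples the integrated cohort into k virtual datasets. In `random`
#' mode each plan draws controls and cases without replacement (plans may
#' overlap with each other); in `per_study` mode there is one plan per
#' batch holding all of that batch's samples; `mixed` mode prepends
#' `k - n_batches` random plans to the per-study plans.
#'
#' @param samples A data frame with columns `sample_id`, `batch`,
#'   `group` (an `expression_cohort`'s `$samples`, or the cohort itself).
#' @param k Number of plans (ignored in `per_study` mode).
#' @param mode `"random"`, `"per_study"` or `"mixed"`.
#' @param sizes Optional list of `c(n_control, n_case)` pairs, one per
#'   random plan; defaults to uniform draws from 5-11 controls and 7-16
#'   cases (capped at availability).
#' @param seed Integer RNG seed.
#'
#' @return An object of class `virtual_plan`: a list of plans, each a
#'   list with `control` and `case` sample-id vectors and a `name`.
#' @export
make_virtual_datasets <- function(samples, k = 8L, mode = c("mixed", "random", "per_study"),
                                  sizes = NULL, seed = 1L) {
  if (inherits(samples, "expression_cohort")) samples <- samples$samples
  mode <- match.arg(mode)
  samples <- as_tibble(samples)
  ctl <- samples$sample_id[samples$group == "control"]
  cas <- samples$sample_id[samples$group == "case"]
  batches <- unique(samples$batch)

  per_study_plans <- lapply(batches, function(b) {
    sub <- samples[samples$batch == b, ]
    list(name = paste0("study_", b),
         control = sub$sample_id[sub$group == "control"],
         case = sub$sample_id[sub$group == "case"])
  })

  n_random <- switch(mode,
                     random = k,
                     per_study = 0L,
                     mixed = max(0L, k - length(batches)))
  if (mode == "per_study") {
    plans <- per_study_plans
  } else {
    random_plans <- with_seed(seed, {
      lapply(seq_len(n_random), function(i) {
        sz <- if (!is.null(sizes)) {
          sizes[[i]]
        } else {
          c(sample(5:11, 1), sample(7:16, 1))
        }
        if (is.null(sizes)) sz <- pmin(sz, c(length(ctl), length(cas)))
        if (sz[1] > length(ctl) || sz[2] > length(cas)) {
          abort(sprintf("Plan %d requests (%d, %d) but only (%d, %d) available.",
                        i, sz[1], sz[2], length(ctl), length(cas)))
        }
        if (sz[1] < 1 || sz[2] < 1) abort("Plan sizes must be >= 1.")
        list(name = sprintf("random_%02d", i),
             control = sort(sample(ctl, sz[1])),
             case = sort(sample(cas, sz[2])))
      })
    })
    plans <- if (mode == "random") random_plans else c(random_plans, per_study_plans)
  }
  for (p in plans) {
    if (length(intersect(p$control, p$case)) > 0) {
      abort("A plan's control and case lists overlap.")
    }
  }
  structure(plans, class = "virtual_plan")
}

#' @export
print.virtual_plan <- function(x, ...) {
  cat("<virtual_plan> ", length(x), " virtual dataset(s)\n", sep = "")
  for (p in x) {
    cat(sprintf("  %-12s %2d control / %2d case\n", p$name,
                length(p$control), length(p$case)))
  }
  invisible(x)
}

#' Score every virtual dataset with the SAM permutation analysis
#'
#' @param cohort An `expression_cohort` (typically batch-corrected).
#' @param plan A `virtual_plan` from [make_virtual_datasets()].
#' @inheritParams sam_permutation
#' @return A named list of `sam_fit` objects, one per plan.
#' @export
score_virtual_datasets <- function(cohort, plan, fdr_cutoff = 0.05,
                                   fc_cutoff = 1.2, B = 200L, seed = 1L) {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(plan, "virtual_plan"))
  fits <- lapply(seq_along(plan), function(i) {
    p <- plan[[i]]
    ids <- c(p$control, p$case)
    missing <- setdiff(ids, colnames(cohort$exprs))
    if (length(missing) > 0) {
      abort(paste0("Plan samples absent from cohort: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    groups <- c(rep("control", length(p$control)), rep("case", length(p$case)))
    sam_permutation(cohort$exprs[, ids, drop = FALSE], groups,
                    fdr_cutoff = fdr_cutoff, fc_cutoff = fc_cutoff,
                    B = B, seed = seed + i)
  })
  names(fits) <- vapply(plan, `[[`, character(1), "name")
  fits
}

#' Consensus signatures across virtual datasets
#'
#' Tallies, per gene, in how many virtual datasets it was called, whether
#' every call shared one direction, and flags it robust when support
#' reaches `m` with a consistent direction.
#'
#' @param fits A list of `sam_fit` objects sharing one gene universe.
#' @param m Support threshold (defaults to 6 of the classic 8 virtual
#'   datasets; must be <= number of fits).
#'
#' @return A tibble (gene, support, direction, direction_consistent,
#'   robust) sorted by support descending then gene id. `direction` is
#'   the common call direction, or `NA` for genes never called or with
#'   conflicting calls.
#' @export
consensus_signatures <- function(fits, m = 6L) {
  if (length(fits) == 0) abort("`fits` must be non-empty.")
  if (m > length(fits)) abort("`m` cannot exceed the number of virtual datasets.")
  universes <- lapply(fits, function(f) sort(f$scores$gene))
  if (!all(vapply(universes[-1], identical, logical(1), universes[[1]]))) {
    abort("All fits must share the same gene universe.")
  }
  calls <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::filter(f$scores, .data$called) |>
      dplyr::transmute(.data$gene, .data$direction, dataset = nm)
  })
  base <- tibble(gene = universes[[1]])
  if (nrow(calls) == 0) {
    return(dplyr::mutate(base, support = 0L, direction = NA_character_,
                         direction_consistent = FALSE, robust = FALSE))
  }
  tallies <- calls |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(support = dplyr::n(),
                     direction_consistent = dplyr::n_distinct(.data$direction) == 1,
                     direction = dplyr::if_else(
                       dplyr::n_distinct(.data$direction) == 1,
                       .data$direction[1], NA_character_),
                     .groups = "drop")
  base |>
    dplyr::left_join(tallies, by = "gene") |>
    dplyr::mutate(support = dplyr::coalesce(.data$support, 0L),
                  direction_consistent = dplyr::coalesce(.data$direction_consistent, FALSE),
                  robust = .data$support >= m & .data$direction_consistent) |>
    dplyr::select("gene", "support", "direction", "direction_consistent",
                  "robust") |>
    dplyr::arrange(dplyr::desc(.data$support), .data$gene)
}

#' End-to-end consensus differential expression
#'
#' Convenience wrapper: plan k virtual datasets, score each with the SAM
#' permutation analysis, and tally consensus signatures.
#'
#' @inheritParams score_virtual_datasets
#' @inheritParams make_virtual_datasets
#' @inheritParams consensus_signatures
#' @return A list with `signatures` (the consensus tibble), `fits` and
#'   `plan`.
#' @export
run_consensus_de <- function(cohort, k = 8L, m = 6L, mode = "mixed",
                             fdr_cutoff = 0.05, fc_cutoff = 1.2,
                             B = 200L, seed = 1L) {
  plan <- make_virtual_datasets(cohort, k = k, mode = mode, seed = seed)
  fits <- score_virtual_datasets(cohort, plan, fdr_cutoff = fdr_cutoff,
                                 fc_cutoff = fc_cutoff, B = B, seed = seed)
  list(signatures = consensus_signatures(fits, m = m), fits = fits,
       plan = plan)
}
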