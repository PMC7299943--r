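#' Study design container
#'
#' A tibble of (`id`, `role`) rows, `role` in `{"discovery", "target"}`,
#' tagged with the relatedness degree and scale labels of the analysis it
#' belongs to.
#'
#' @param discovery_ids,target_ids Disjoint character id vectors.
#' @param degree_label One of `"unrelated"`, `"1"`, `"2"`, `"3"`.
#' @param scale_label `"large"` or `"small"`.
#' @param seed Integer seed that produced the design.
#' @return A tibble of class `study_design`.
#' @export
study_design <- function(discovery_ids, target_ids,
                         degree_label = "unrelated",
                         scale_label = "small", seed = NA_integer_) {
  degree_label <- match.arg(degree_label, c("unrelated", "1", "2", "3"))
  scale_label <- match.arg(scale_label, c("large", "small"))
  if (anyDuplicated(c(discovery_ids, target_ids))) {
    stop("discovery and target ids must be disjoint and free of duplicates",
         call. = FALSE)
  }
  out <- tibble::tibble(
    id = c(discovery_ids, target_ids),
    role = rep(c("discovery", "target"),
               c(length(discovery_ids), length(target_ids)))
  )
  attr(out, "degree_label") <- degree_label
  attr(out, "scale_label") <- scale_label
  attr(out, "seed") <- as.integer(seed)
  class(out) <- unique(c("study_design", class(out)))
  out
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design %s-scale, %s> %d discovery + %d target\n",
              attr(x, "scale_label"), attr(x, "degree_label"),
              sum(x$role == "discovery"), sum(x$role == "target")))
  invisible(x)
}

#' Ids of one role of a design
#' @param design A [study_design()].
#' @param role `"discovery"` or `"target"`.
#' @return Character vector of ids.
#' @export
design_ids <- function(design, role = c("discovery", "target")) {
  role <- match.arg(role)
  design$id[design$role == role]
}

#' Prune a sample to mutually unrelated individuals
#'
#' Iteratively removes individuals until no retained pair has a relationship
#' (or kinship) above `threshold`: while violating pairs remain, one
#' violating pair is drawn uniformly at random and one of its two members is
#' removed, also uniformly at random. This is deliberately the pair-at-a-time
#' random exclusion used in biobank practice, not a maximum independent set.
#'
#' @param pairs Either a [rel_matrix()] (off-diagonal entries are the
#'   pairwise values) or a tibble with columns `id_i`, `id_j` and a value
#'   column (`value` or `phi`).
#' @param threshold Pairs with value strictly greater than this are
#'   violations (default 0.05, the conventional genomic-relationship cut).
#' @param seed Integer seed for the random removals.
#' @param ids Optional universe of ids (defaults to the ids appearing in
#'   `pairs`); ids with no violating pair are always retained.
#' @return Character vector of retained ids (original order).
#' @export
prune_unrelated <- function(pairs, threshold = 0.05, seed = 1L, ids = NULL) {
  stopifnot(threshold > 0)
  if (inherits(pairs, "rel_matrix")) {
    universe <- ids %||% pairs$ids
    tbl <- tidy(pairs, diagonal = FALSE)
  } else {
    tbl <- tibble::as_tibble(pairs)
    val_col <- intersect(c("value", "phi"), names(tbl))[1]
    if (is.na(val_col)) stop("pairs need a `value` or `phi` column", call. = FALSE)
    tbl$value <- tbl[[val_col]]
    universe <- ids %||% unique(c(tbl$id_i, tbl$id_j))
  }
  edges <- tbl[tbl$value > threshold & tbl$id_i %in% universe &
                 tbl$id_j %in% universe, c("id_i", "id_j")]
  removed <- character(0)
  withr::with_seed(seed, {
    while (nrow(edges) > 0) {
      k <- sample.int(nrow(edges), 1L)
      victim <- if (stats::runif(1) < 0.5) edges$id_i[k] else edges$id_j[k]
      removed <- c(removed, victim)
      edges <- edges[edges$id_i != victim & edges$id_j != victim, , drop = FALSE]
    }
  })
  setdiff(universe, removed)
}

#' Connected components of the degree-d relative graph
#'
#' Individuals are nodes; pairs of the requested relatedness degree are
#' undirected edges. Returns the connected components ("family groups") of
#' that graph.
#'
#' @param pairs Kinship tibble with columns `id_i`, `id_j`, `degree` (from
#'   [estimate_kinship_all()] or [pedigree_kinship()]).
#' @param degree Relatedness degree `"1"`, `"2"` or `"3"` selecting the
#'   edges.
#' @return A tibble with columns `id`, `component` (integer label),
#'   `component_size` and `n_links` (the node's degree inside its
#'   component).
#' @export
build_family_graph <- function(pairs, degree = c("1", "2", "3")) {
  degree <- match.arg(as.character(degree), c("1", "2", "3"))
  edges <- pairs[pairs$degree == degree, c("id_i", "id_j"), drop = FALSE]
  if (nrow(edges) == 0) {
    return(tibble::tibble(id = character(0), component = integer(0),
                          component_size = integer(0), n_links = integer(0)))
  }
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(gr)
  tibble::tibble(
    id = igraph::V(gr)$name,
    component = as.integer(comp$membership),
    component_size = as.integer(comp$csize[comp$membership]),
    n_links = as.integer(igraph::degree(gr))
  )
}

#' Greedy selection of highly related individuals
#'
#' Takes whole components of the relative graph in decreasing size order
#' (ties broken by the lexicographically smallest member id) until `n_total`
#' individuals are selected; if the last component overshoots, its members
#' with the most within-component links are kept first (ties again by id).
#' By construction the selected set has higher average relatedness than a
#' random subset of the same pool.
#'
#' @param components Output of [build_family_graph()].
#' @param n_total Number of individuals to select.
#' @return Character vector of selected ids.
#' @export
select_related_subset <- function(components, n_total) {
  stopifnot(nrow(components) > 0 || n_total == 0)
  if (n_total > nrow(components)) {
    stop(sprintf("cannot select %d individuals from a pool of %d (short by %d)",
                 n_total, nrow(components), n_total - nrow(components)),
         call. = FALSE)
  }
  comp_order <- components |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(size = dplyr::n(), min_id = min(.data$id),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$min_id)
  selected <- character(0)
  for (k in seq_len(nrow(comp_order))) {
    members <- components[components$component == comp_order$component[k], ]
    members <- members[order(-members$n_links, members$id), ]
    need <- n_total - length(selected)
    if (need <= 0) break
    selected <- c(selected, utils::head(members$id, need))
  }
  selected
}

#' Substitute relatives into an existing design
#'
#' Replaces a seeded random subset of a base design's individuals with the
#' supplied relatives, keeping the total sample size fixed. Replacement
#' slots are drawn uniformly across the whole design, so the relatives
#' inherit the design's discovery/target split fractions in expectation.
#'
#' @param base A [study_design()].
#' @param relatives Character ids to introduce (disjoint from the base ids).
#' @param seed Integer seed.
#' @param degree_label Degree label for the returned design.
#' @return A [study_design()] of identical total size.
#' @export
substitute_relatives <- function(base, relatives, seed = 1L,
                                 degree_label = "1") {
  n_rel <- length(relatives)
  if (n_rel > nrow(base)) {
    stop(sprintf("%d relatives exceed the design size %d", n_rel, nrow(base)),
         call. = FALSE)
  }
  if (n_rel == 0) return(base)
  overlap <- intersect(relatives, base$id)
  if (length(overlap)) {
    stop("relatives already present in the base design: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  new_tbl <- base
  withr::with_seed(seed, {
    slots <- sample.int(nrow(base), n_rel)
    new_tbl$id[slots] <- relatives
  })
  study_design(new_tbl$id[new_tbl$role == "discovery"],
               new_tbl$id[new_tbl$role == "target"],
               degree_label = degree_label,
               scale_label = attr(base, "scale_label"), seed = seed)
}

#' Split ids into discovery and target samples
#'
#' Seeded random partition into `discovery_fraction` discovery and the rest
#' target. With `related_targets = TRUE`, targets are chosen so that every
#' target has at least one relative (a pair listed in `pairs`) left inside
#' the discovery set; with `related_targets = FALSE`, targets are chosen
#' among individuals with no listed relative in the pool. `NULL` (default)
#' is a plain random split.
#'
#' @param ids Character pool of ids.
#' @param discovery_fraction Fraction in (0, 1) assigned to discovery.
#' @param seed Integer seed.
#' @param related_targets `NULL`, `TRUE` (TA-style targets) or `FALSE`
#'   (TB-style targets).
#' @param pairs Kinship tibble (`id_i`, `id_j`), required when
#'   `related_targets` is not `NULL`.
#' @param degree_label,scale_label Labels for the returned design.
#' @return A [study_design()].
#' @export
split_design <- function(ids, discovery_fraction = 0.8, seed = 1L,
                         related_targets = NULL, pairs = NULL,
                         degree_label = "unrelated", scale_label = "small") {
  stopifnot(discovery_fraction > 0, discovery_fraction < 1)
  n <- length(ids)
  n_disc <- round(discovery_fraction * n)
  n_disc <- min(max(n_disc, 1L), n - 1L)
  n_target <- n - n_disc
  if (is.null(related_targets)) {
    withr::with_seed(seed, {
      target <- sample(ids, n_target)
    })
    return(study_design(setdiff(ids, target), target,
                        degree_label = degree_label,
                        scale_label = scale_label, seed = seed))
  }
  stopifnot(!is.null(pairs))
  prs <- pairs[pairs$id_i %in% ids & pairs$id_j %in% ids, c("id_i", "id_j")]
  partner <- split(c(prs$id_j, prs$id_i), c(prs$id_i, prs$id_j))
  has_rel <- ids[ids %in% names(partner)]
  withr::with_seed(seed, {
    if (isTRUE(related_targets)) {
      candidates <- sample(has_rel)
      target <- character(0)
      taken <- character(0)
      for (cand in candidates) {
        if (length(target) >= n_target) break
        # keep at least one partner out of the target set
        if (any(!(partner[[cand]] %in% taken))) {
          # reserve one partner for discovery by never targeting the last one
          free <- setdiff(partner[[cand]], taken)
          if (length(free) >= 1) {
            target <- c(target, cand)
            taken <- c(taken, cand)
          }
        }
      }
      # a partner that later became a target could strand an earlier target;
      # verify and drop stranded targets
      target <- target[vapply(target, function(t)
        any(!(partner[[t]] %in% target)), logical(1))]
      if (length(target) < n_target) {
        stop(sprintf(paste0("cannot form %d related targets: only %d ",
                            "individuals have a relative left in discovery"),
                     n_target, length(target)), call. = FALSE)
      }
      target <- target[seq_len(n_target)]
    } else {
      lonely <- setdiff(ids, has_rel)
      if (length(lonely) < n_target) {
        stop(sprintf(paste0("cannot form %d unrelated targets: only %d ",
                            "individuals have no relative in the pool"),
                     n_target, length(lonely)), call. = FALSE)
      }
      target <- sample(lonely, n_target)
    }
  })
  study_design(setdiff(ids, target), target, degree_label = degree_label,
               scale_label = scale_label, seed = seed)
}
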