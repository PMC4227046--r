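#' Specification for synthetic dendritic trees
#'
#' Collects the per-group distributions (primary-dendrite count, bifurcation
#' count, total dendritic length, terminal-segment length) used by
#' [generate_tree()], plus the depth profile of each dendrite below the slice
#' surface. Reconstructions from slices are partial: only radial dendrites
#' staying within the slice plane are analyzed, so each synthetic dendrite is
#' laid out in a plane at a constant depth; dendrites drawn deeper than the
#' 50 um inclusion limit exercise the slice filter.
#'
#' @param genotype,pattern group labels (see [mn_reference_table()]).
#' @param table distribution table.
#' @param z_range depth range (um) for in-slice dendrites.
#' @param deep_fraction fraction of dendrites rendered below the inclusion
#'   limit (0 by default: the printed Table entries describe post-filter
#'   trees).
#' @param deep_z depth range (um) for those plunging dendrites.
#' @return an `mn_tree_spec` list.
#' @export
tree_spec <- function(genotype = "WT", pattern = "immediate",
                      table = mn_reference_table(),
                      z_range = c(0, 40), deep_fraction = 0,
                      deep_z = c(55, 120)) {
  gs <- group_spec(genotype, pattern, table = table, mmo_prob = 0)
  need <- c("n_primary", "n_branch_points", "total_length", "terminal_segment")
  missing <- setdiff(need, gs$properties$property)
  if (length(missing)) {
    abort(paste0("tree spec lacks: ", paste(missing, collapse = ", ")))
  }
  structure(list(genotype = genotype, pattern = pattern,
                 properties = gs$properties, z_range = z_range,
                 deep_fraction = deep_fraction, deep_z = deep_z,
                 spec = gs),
            class = "mn_tree_spec")
}

new_morphology <- function(nodes, ground_truth = NULL) {
  nodes <- tibble::as_tibble(nodes)
  structure(nodes, ground_truth = ground_truth,
            class = c("mn_morphology", class(nodes)))
}

#' Generate a synthetic dendritic tree (SWC node table)
#'
#' Builds a rooted tree with the drawn number of primary dendrites and
#' bifurcation points (bifurcations distributed uniformly among dendrites,
#' random binary topology per dendrite), draws all segment lengths from the
#' terminal-segment distribution and rescales them so the summed length
#' equals the drawn total length. Nodes are laid every 10 um along straight
#' segments; each dendrite lies in a plane at a constant depth below the
#' slice surface (z, positive downward).
#'
#' @param spec an [tree_spec()].
#' @param seed integer seed.
#' @param node_spacing spacing of SWC nodes along segments (um).
#' @return an `mn_morphology` tibble (SWC columns `id`, `type`, `x`, `y`,
#'   `z`, `radius`, `parent`) with a `ground_truth` attribute recording the
#'   drawn metrics.
#' @export
generate_tree <- function(spec, seed = NULL, node_spacing = 10) {
  stopifnot(inherits(spec, "mn_tree_spec"))
  gs <- spec$spec
  with_seed(seed, {
    p <- max(1L, as.integer(round(draw_property(gs, "n_primary", 1))))
    b_total <- max(0L, as.integer(round(draw_property(gs, "n_branch_points", 1))))
    l_target <- draw_property(gs, "total_length", 1) * 1000  # mm -> um
    # bifurcations spread across dendrites
    b_per <- tabulate(sample.int(p, b_total, replace = TRUE), nbins = p)
    n_seg <- 2 * b_per + 1
    seg_len <- draw_property(gs, "terminal_segment", sum(n_seg))
    seg_len <- seg_len * l_target / sum(seg_len)
    depth <- ifelse(runif(p) < spec$deep_fraction,
                    runif(p, spec$deep_z[1], spec$deep_z[2]),
                    runif(p, spec$z_range[1], spec$z_range[2]))

    nodes <- list(tibble::tibble(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                                 radius = 10, parent = -1L))
    next_id <- 2L
    seg_ptr <- 0L
    for (d in seq_len(p)) {
      # random binary topology: split random terminal segments b_per[d] times
      segs <- list(list(parent_seg = 0L))          # stem
      term <- 1L
      for (s in seq_len(b_per[d])) {
        pick <- term[sample.int(length(term), 1)]
        segs[[length(segs) + 1L]] <- list(parent_seg = pick)
        segs[[length(segs) + 1L]] <- list(parent_seg = pick)
        term <- c(setdiff(term, pick),
                  length(segs) - 1L, length(segs))
      }
      lens <- seg_len[seg_ptr + seq_along(segs)]
      seg_ptr <- seg_ptr + length(segs)
      # longest tip-to-soma path of this dendrite (known from the topology)
      path_of_seg <- numeric(length(segs))
      for (s in seq_along(segs)) {
        ps <- segs[[s]]$parent_seg
        path_of_seg[s] <- lens[s] + if (ps == 0L) 0 else path_of_seg[ps]
      }
      max_path <- max(path_of_seg)
      # depth grows linearly with path distance (z-slope <= 0.9 so every
      # inter-node step keeps a horizontal component); inter-node 3D distances
      # stay exact, so total length is preserved
      z_slope <- min(depth[d] / max_path, 0.9)
      theta0 <- 2 * pi * (d - 1) / p + runif(1, -0.2, 0.2)
      # per-segment metadata filled while walking the topology in order
      seg_tail_id <- integer(length(segs))   # SWC id of each segment's tip
      seg_tail_xy <- matrix(0, length(segs), 2)
      seg_tail_path <- numeric(length(segs))
      seg_dir <- numeric(length(segs))
      h_frac <- sqrt(1 - z_slope^2)
      for (s in seq_along(segs)) {
        ps <- segs[[s]]$parent_seg
        if (ps == 0L) {
          start_xy <- c(0, 0)
          path0 <- 0
          dir <- theta0
          parent_id <- 1L
        } else {
          start_xy <- seg_tail_xy[ps, ]
          path0 <- seg_tail_path[ps]
          dir <- seg_dir[ps] + sample(c(-1, 1), 1) * runif(1, 0.35, 0.8)
          parent_id <- seg_tail_id[ps]
        }
        len <- lens[s]
        n_nodes <- max(1L, ceiling(len / node_spacing))
        dist <- c(seq_len(n_nodes - 1) * node_spacing, len)
        if (n_nodes == 1L) dist <- len
        xs <- start_xy[1] + dist * h_frac * cos(dir)
        ys <- start_xy[2] + dist * h_frac * sin(dir)
        zs <- (path0 + dist) * z_slope
        ids <- next_id - 1L + seq_len(n_nodes)
        parents <- c(parent_id, ids[-n_nodes])
        nodes[[length(nodes) + 1L]] <- tibble::tibble(
          id = ids, type = 3L, x = xs, y = ys, z = zs,
          radius = 1, parent = parents)
        next_id <- next_id + n_nodes
        seg_tail_id[s] <- ids[n_nodes]
        seg_tail_xy[s, ] <- c(xs[n_nodes], ys[n_nodes])
        seg_tail_path[s] <- path0 + len
        seg_dir[s] <- dir
      }
      depth[d] <- z_slope * max_path
    }
    tab <- dplyr::bind_rows(nodes)
    gt <- list(n_primary = p, n_branch_points = b_total,
               total_length = l_target / 1000, depth = depth,
               n_deep = sum(depth > 50))
    new_morphology(tab, ground_truth = gt)
  })
}

#' Write / read SWC morphology files
#'
#' Standard 7-column SWC (`id type x y z radius parent`), units um, soma as
#' a single type-1 node, `#` comments allowed.
#'
#' @param m an `mn_morphology`.
#' @param path file path.
#' @return `read_swc()` returns a validated `mn_morphology`;
#'   `write_swc()` returns `path` invisibly.
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "mn_morphology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export (id type x y z radius parent), units um", con)
  utils::write.table(
    data.frame(m$id, m$type, format(m$x, digits = 8),
               format(m$y, digits = 8), format(m$z, digits = 8),
               format(m$radius, digits = 6), m$parent),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  if (ncol(raw) != 7) abort("malformed SWC: expected 7 columns")
  nodes <- tibble::as_tibble(raw)
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  validate_morphology(new_morphology(nodes))
}

validate_morphology <- function(m) {
  if (any(duplicated(m$id))) abort("duplicated SWC node ids")
  roots <- which(m$parent == -1L)
  if (length(roots) != 1) abort("SWC must contain exactly one root node")
  known <- c(-1L, m$id)
  orphan <- which(!(m$parent %in% known))
  if (length(orphan)) {
    abort(sprintf("node %d references missing parent %d",
                  m$id[orphan[1]], m$parent[orphan[1]]))
  }
  # acyclicity / connectivity: every node must reach the root
  idx <- match(m$parent, m$id)
  n <- nrow(m)
  for (i in seq_len(n)) {
    steps <- 0L
    j <- i
    while (m$parent[j] != -1L) {
      j <- idx[j]
      steps <- steps + 1L
      if (steps > n) abort(sprintf("cycle detected at node %d", m$id[i]))
    }
  }
  m
}

#' Slice-plane inclusion filter
#'
#' Removes every dendritic subtree that plunges deeper than `z_limit` below
#' the slice surface (z positive downward, surface at z = 0): a node deeper
#' than the limit is removed together with all its descendants, so a primary
#' dendrite whose trunk plunges is pruned entirely.
#'
#' @param m an `mn_morphology`.
#' @param z_limit inclusion depth in um.
#' @return the filtered `mn_morphology`.
#' @export
apply_slice_filter <- function(m, z_limit = 50) {
  stopifnot(inherits(m, "mn_morphology"))
  idx <- match(m$parent, m$id)
  bad <- m$z > z_limit & m$parent != -1L
  # propagate removal to descendants (parents precede children after a
  # topological ordering; iterate to closure to stay order-agnostic)
  repeat {
    grow <- !bad & !is.na(idx) & bad[idx]
    if (!any(grow, na.rm = TRUE)) break
    bad <- bad | (grow %in% TRUE)
  }
  keep <- m[!bad, , drop = FALSE]
  new_morphology(keep, ground_truth = attr(m, "ground_truth"))
}

#' Dendritic morphometrics of a reconstruction
#'
#' Computes, from a (filtered) morphology: the number of primary dendrites
#' (children of the soma), the number of branching points (non-soma nodes
#' with two or more children — higher-order nodes count once), the total
#' dendritic length in mm (sum of inter-node Euclidean distances), the
#' dendritic paths (trajectory length from the tip of every terminal segment
#' to the soma attachment, um) and the terminal segment lengths (tip to the
#' nearest branching point, um).
#'
#' @param m an `mn_morphology`.
#' @param soma_area optional externally measured soma area (um^2), carried
#'   through unchanged.
#' @return A list of class `mn_morpho_metrics`: `n_primary`,
#'   `n_branch_points`, `total_length` (mm), `dendritic_paths` (um),
#'   `terminal_segment_lengths` (um), `soma_area`.
#' @export
compute_metrics <- function(m, soma_area = NA_real_) {
  stopifnot(inherits(m, "mn_morphology"))
  n <- nrow(m)
  root <- which(m$parent == -1L)[1]
  idx <- match(m$parent, m$id)
  edge_len <- numeric(n)
  has_par <- !is.na(idx)
  edge_len[has_par] <- sqrt((m$x - m$x[idx])^2 + (m$y - m$y[idx])^2 +
                              (m$z - m$z[idx])^2)[has_par]
  n_children <- tabulate(idx[has_par], nbins = n)
  is_tip <- n_children == 0 & seq_len(n) != root
  is_branch <- n_children >= 2 & seq_len(n) != root
  paths <- numeric(0)
  term_lens <- numeric(0)
  for (i in which(is_tip)) {
    d_path <- 0
    d_term <- 0
    j <- i
    past_branch <- FALSE
    while (!is.na(idx[j])) {
      d_path <- d_path + edge_len[j]
      if (!past_branch) d_term <- d_term + edge_len[j]
      j2 <- idx[j]
      if (is_branch[j2] || j2 == root) past_branch <- TRUE
      j <- j2
    }
    paths <- c(paths, d_path)
    term_lens <- c(term_lens, d_term)
  }
  structure(list(
    n_primary = sum(idx == root, na.rm = TRUE),
    n_branch_points = sum(is_branch),
    total_length = sum(edge_len) / 1000,
    dendritic_paths = paths,
    terminal_segment_lengths = term_lens,
    soma_area = soma_area
  ), class = "mn_morpho_metrics")
}

#' @export
print.mn_morpho_metrics <- function(x, ...) {
  cat("<mn_morpho_metrics> ", x$n_primary, " primary dendrites, ",
      x$n_branch_points, " branching points, ",
      signif(x$total_length, 3), " mm total length, ",
      length(x$dendritic_paths), " terminal tips\n", sep = "")
  invisible(x)
}

#' Tidy one or several morphometric results
#'
#' @param x an `mn_morpho_metrics`.
#' @param ... unused.
#' @return one-row tibble of the scalar metrics (path/terminal lists
#'   summarized by their means and counts).
#' @export
tidy.mn_morpho_metrics <- function(x, ...) {
  tibble::tibble(
    n_primary = x$n_primary,
    n_branch_points = x$n_branch_points,
    total_length = x$total_length,
    mean_dendritic_path = mean(x$dendritic_paths),
    n_paths = length(x$dendritic_paths),
    mean_terminal_segment = mean(x$terminal_segment_lengths),
    soma_area = x$soma_area
  )
}
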