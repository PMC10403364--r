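# Neuron skeletons: SWC I/O, pruning, resampling, volume masks and cable
# fraction.

#' Neuron skeleton
#'
#' @param nodes data.frame with SWC columns `id`, `type`, `x`, `y`, `z`
#'   (micrometers), `radius`, `parent` (`-1` for the root).
#' @return validated data.frame of class `neuron_skeleton`.
#' @export
neuron_skeleton <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  stopifnot(all(need %in% names(nodes)), nrow(nodes) >= 1)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (sum(nodes$parent == -1) != 1) stop("skeleton must have exactly one root")
  known <- nodes$parent %in% c(-1, nodes$id)
  if (!all(known)) stop("parent ids missing from the skeleton")
  class(nodes) <- c("neuron_skeleton", "data.frame")
  nodes
}

#' Read a skeleton from an SWC file
#'
#' Standard whitespace-separated 7-column SWC; lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @return a [neuron_skeleton()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "radius",
                                  "parent"))
  neuron_skeleton(tab)
}

#' Write a skeleton to an SWC file
#' @param skel a [neuron_skeleton()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path) {
  stopifnot(inherits(skel, "neuron_skeleton"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  write.table(as.data.frame(skel), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ids of node_id and all its descendants
subtree_ids <- function(skel, node_id) {
  children <- split(skel$id, skel$parent)
  out <- node_id
  frontier <- node_id
  while (length(frontier) > 0) {
    nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Prune a skeleton at a node
#'
#' Keeps either the subtree rooted at `node_id` (`keep = "distal"`, the
#' default, e.g. isolating a dendritic arbor) or everything except that
#' node's strict descendants (`keep = "proximal"`). In distal mode the
#' prune node becomes the new root.
#'
#' @param skel a [neuron_skeleton()].
#' @param node_id node at which to prune; must exist in the skeleton.
#' @param keep `"distal"` or `"proximal"`.
#' @return a pruned [neuron_skeleton()].
#' @export
prune_skeleton <- function(skel, node_id, keep = c("distal", "proximal")) {
  stopifnot(inherits(skel, "neuron_skeleton"))
  keep <- match.arg(keep)
  if (!node_id %in% skel$id) stop("prune node not in skeleton")
  sub <- subtree_ids(skel, node_id)
  kept <- if (keep == "distal") {
    out <- skel[skel$id %in% sub, , drop = FALSE]
    out$parent[out$id == node_id] <- -1
    out
  } else {
    skel[!(skel$id %in% setdiff(sub, node_id)), , drop = FALSE]
  }
  rownames(kept) <- NULL
  neuron_skeleton(kept)
}

#' Resample a skeleton at a fixed step
#'
#' Replaces each parent-child edge by `n_seg = max(1, round(L / step))`
#' equal segments, inserting evenly spaced interior nodes, to obtain an
#' approximately even node distribution along the cable.
#'
#' @param skel a [neuron_skeleton()].
#' @param step resampling step in micrometers (default 1).
#' @return a resampled [neuron_skeleton()] with renumbered node ids.
#' @export
resample_skeleton <- function(skel, step = 1) {
  stopifnot(inherits(skel, "neuron_skeleton"), step > 0)
  df <- as.data.frame(skel)
  # map old ids to new ids of the original nodes first
  new_id_of <- setNames(seq_len(nrow(df)), df$id)
  nodes <- data.frame(id = unname(new_id_of[as.character(df$id)]),
                      type = df$type, x = df$x, y = df$y, z = df$z,
                      radius = df$radius,
                      parent = ifelse(df$parent == -1, -1,
                                      unname(new_id_of[as.character(df$parent)])))
  next_id <- nrow(df) + 1
  extra <- list()
  for (i in seq_len(nrow(df))) {
    if (df$parent[i] == -1) next
    p <- df[df$id == df$parent[i], ]
    L <- sqrt((df$x[i] - p$x)^2 + (df$y[i] - p$y)^2 + (df$z[i] - p$z)^2)
    n_seg <- max(1, round(L / step))
    if (n_seg == 1) next
    f <- seq_len(n_seg - 1) / n_seg
    ids <- next_id:(next_id + n_seg - 2)
    next_id <- next_id + n_seg - 1
    extra[[length(extra) + 1]] <- data.frame(
      id = ids, type = df$type[i],
      x = p$x + f * (df$x[i] - p$x),
      y = p$y + f * (df$y[i] - p$y),
      z = p$z + f * (df$z[i] - p$z),
      radius = p$radius + f * (df$radius[i] - p$radius),
      parent = c(nodes$parent[i], ids[-length(ids)]))
    # reattach the child to the last interior node
    nodes$parent[i] <- ids[length(ids)]
  }
  out <- rbind(nodes, do.call(rbind, extra))
  rownames(out) <- NULL
  neuron_skeleton(out)
}

#' Axis-aligned box volume mask
#'
#' @param lower,upper length-3 numeric corners (micrometers).
#' @param name mask name.
#' @return object of class `volume_mask` with an inside test.
#' @export
box_mask <- function(lower, upper, name = "box") {
  stopifnot(length(lower) == 3, length(upper) == 3, all(lower < upper))
  structure(list(name = name, kind = "box", lower = lower, upper = upper),
            class = "volume_mask")
}

#' Voxel volume mask
#'
#' A 3-d logical array on a regular grid; a point is inside when the voxel
#' containing it is TRUE.
#'
#' @param voxels 3-d logical array.
#' @param origin coordinates of the lower corner of voxel `[1,1,1]`.
#' @param spacing voxel edge lengths, length 1 or 3 (micrometers).
#' @param name mask name.
#' @return object of class `volume_mask`.
#' @export
voxel_mask <- function(voxels, origin = c(0, 0, 0), spacing = 1,
                       name = "voxels") {
  stopifnot(is.logical(voxels), length(dim(voxels)) == 3,
            length(origin) == 3, all(spacing > 0))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  structure(list(name = name, kind = "voxels", voxels = voxels,
                 origin = origin, spacing = spacing),
            class = "volume_mask")
}

#' Test points against a volume mask
#' @param mask a [box_mask()] or [voxel_mask()].
#' @param points n x 3 matrix of coordinates.
#' @return logical vector, one entry per point.
#' @export
mask_contains <- function(mask, points) {
  stopifnot(inherits(mask, "volume_mask"))
  points <- matrix(points, ncol = 3)
  if (mask$kind == "box") {
    return(points[, 1] >= mask$lower[1] & points[, 1] <= mask$upper[1] &
             points[, 2] >= mask$lower[2] & points[, 2] <= mask$upper[2] &
             points[, 3] >= mask$lower[3] & points[, 3] <= mask$upper[3])
  }
  dims <- dim(mask$voxels)
  idx <- sapply(1:3, function(a) {
    floor((points[, a] - mask$origin[a]) / mask$spacing[a]) + 1
  })
  idx <- matrix(idx, ncol = 3)
  ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
    idx[, 2] >= 1 & idx[, 2] <= dims[2] &
    idx[, 3] >= 1 & idx[, 3] <= dims[3]
  inside <- logical(nrow(points))
  inside[ok] <- mask$voxels[idx[ok, , drop = FALSE]]
  inside
}

#' Fraction of skeleton cable inside a volume
#'
#' Optionally prunes the skeleton at a stored prune point, resamples it at
#' a fixed step for an even node distribution, and returns the number of
#' nodes inside the volume divided by the total number of nodes.
#'
#' @param skel a [neuron_skeleton()].
#' @param mask a [box_mask()] or [voxel_mask()].
#' @param prune_node optional node id; when given, the skeleton is pruned
#'   to that node's subtree before resampling.
#' @param step resampling step, micrometers (default 1).
#' @return fraction in `[0, 1]`.
#' @export
cable_fraction_in_volume <- function(skel, mask, prune_node = NULL,
                                     step = 1) {
  stopifnot(inherits(skel, "neuron_skeleton"))
  if (!is.null(prune_node)) skel <- prune_skeleton(skel, prune_node)
  rs <- resample_skeleton(skel, step = step)
  inside <- mask_contains(mask, cbind(rs$x, rs$y, rs$z))
  sum(inside) / length(inside)
}
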