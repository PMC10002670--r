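#' Build a region ontology tree
#'
#' Reference atlases organize regions in a hierarchy. An `ontology` is a rooted
#' tree of `(id, name, parent_id)` records: exactly one record has a missing
#' `parent_id` (the root), IDs are unique, names nonempty, and parent links
#' contain no cycles.
#'
#' @param records data.frame (or list of rows) with columns `id`, `name`,
#'   `parent_id`; `parent_id` is `NA` for the root.
#' @return object of class `ontology` with fields `nodes` (data.table),
#'   `root` (integer id) and `parent` (named lookup vector).
#' @export
build_ontology <- function(records) {
  if (is.data.frame(records)) {
    nodes <- data.table::as.data.table(records)
  } else if (is.list(records) && length(records)) {
    nodes <- data.table::rbindlist(lapply(records, function(r) {
      list(id = r[[1]], name = r[[2]],
           parent_id = if (is.null(r[[3]]) || is.na(r[[3]])) NA else r[[3]])
    }))
  } else {
    stop("`records` must be a nonempty data.frame or list", call. = FALSE)
  }
  if (!nrow(nodes)) stop("`records` must be nonempty", call. = FALSE)
  nodes[, `:=`(id = as.integer(id), parent_id = as.integer(parent_id),
               name = as.character(name))]
  if (anyDuplicated(nodes$id)) {
    stop("ontology structure error: duplicate IDs", call. = FALSE)
  }
  if (any(!nzchar(nodes$name)) || anyNA(nodes$name)) {
    stop("ontology structure error: names must be nonempty", call. = FALSE)
  }
  roots <- nodes$id[is.na(nodes$parent_id)]
  if (length(roots) != 1L) {
    stop(sprintf("ontology structure error: found %d roots, need exactly 1",
                 length(roots)), call. = FALSE)
  }
  known <- nodes$parent_id[!is.na(nodes$parent_id)]
  if (!all(known %in% nodes$id)) {
    stop("ontology structure error: parent_id not among IDs", call. = FALSE)
  }
  parent <- nodes$parent_id
  names(parent) <- as.character(nodes$id)
  # cycle check: every node must reach the root in <= n steps
  n <- nrow(nodes)
  for (id in nodes$id) {
    cur <- id
    steps <- 0L
    while (!is.na(parent[[as.character(cur)]])) {
      cur <- parent[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) {
        stop("ontology structure error: cycle in parent links", call. = FALSE)
      }
    }
  }
  structure(list(nodes = nodes, root = roots, parent = parent),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d nodes, root id %d (%s)\n", nrow(x$nodes),
              x$root, x$nodes$name[x$nodes$id == x$root]))
  invisible(x)
}

#' Ancestors of an ontology node
#' @param ontology an [build_ontology()] tree.
#' @param id node ID.
#' @param include_self prepend `id` itself.
#' @return integer vector from nearest ancestor (or self) up to the root.
#' @export
ancestors <- function(ontology, id, include_self = FALSE) {
  stopifnot(inherits(ontology, "ontology"))
  id <- as.integer(id)
  if (!id %in% ontology$nodes$id) {
    stop(sprintf("unknown ontology id %d", id), call. = FALSE)
  }
  out <- if (include_self) id else integer()
  cur <- id
  repeat {
    p <- ontology$parent[[as.character(cur)]]
    if (is.na(p)) break
    out <- c(out, p)
    cur <- p
  }
  out
}

#' Read / write an ontology as CSV
#'
#' CSV dialect: header `id,name,parent_id`, empty `parent_id` marks the root.
#' @param path CSV file.
#' @export
read_ontology_csv <- function(path) {
  dt <- data.table::fread(path, colClasses = list(
    integer = c("id", "parent_id"), character = "name"))
  build_ontology(dt)
}

#' @rdname read_ontology_csv
#' @param ontology tree to serialize.
#' @export
write_ontology_csv <- function(ontology, path) {
  stopifnot(inherits(ontology, "ontology"))
  data.table::fwrite(ontology$nodes[, c("id", "name", "parent_id")], path)
  invisible(path)
}

#' Collapse an ontology into a customized intermediate hierarchy
#'
#' Verifying atlas registration (and reporting loads) at the finest atlas
#' granularity is rarely possible; instead a user selects a set of ontology
#' nodes ("the intermediate hierarchy") and every atlas label is pooled into
#' its *nearest* selected ancestor-or-self. Labels with no selected ancestor
#' map to the reserved `UNMAPPED` ID (-1) and are reported.
#'
#' When the selection contains both a node and one of its descendants, the
#' nearest (most specific) selected node wins — consistent with iteratively
#' moving one hierarchy level up only where verification fails.
#'
#' @param ontology an [build_ontology()] tree.
#' @param selected_ids ontology IDs defining the custom level (nonempty).
#' @param volume the [atlas_volume()] whose labels must be covered.
#' @return object of class `custom_hierarchy`: `selected_ids`, `leaf_map`
#'   (named integer vector, atlas label -> custom ID or -1), `names`
#'   (custom ID -> name), `unmapped` (labels that fell through).
#' @export
collapse_to_custom <- function(ontology, selected_ids, volume) {
  stopifnot(inherits(ontology, "ontology"), inherits(volume, "atlas_volume"))
  selected_ids <- as.integer(selected_ids)
  if (!length(selected_ids)) {
    stop("`selected_ids` must be nonempty", call. = FALSE)
  }
  if (!all(selected_ids %in% ontology$nodes$id)) {
    stop("selected IDs must exist in the ontology", call. = FALSE)
  }
  labels <- region_ids(volume)
  if (!all(labels %in% ontology$nodes$id)) {
    stop("volume labels missing from ontology", call. = FALSE)
  }
  sel <- unique(selected_ids)
  leaf_map <- vapply(labels, function(lab) {
    chain <- ancestors(ontology, lab, include_self = TRUE)
    hit <- chain[chain %in% sel]
    if (length(hit)) hit[1] else -1L  # chain is ordered self -> root
  }, integer(1))
  names(leaf_map) <- as.character(labels)
  nm <- ontology$nodes$name[match(sel, ontology$nodes$id)]
  names(nm) <- as.character(sel)
  if (any(leaf_map == -1L)) {
    message(sprintf("%d atlas label(s) have no selected ancestor (UNMAPPED)",
                    sum(leaf_map == -1L)))
  }
  structure(
    list(selected_ids = sel, leaf_map = leaf_map, names = nm,
         unmapped = labels[leaf_map == -1L]),
    class = "custom_hierarchy"
  )
}

#' @export
print.custom_hierarchy <- function(x, ...) {
  cat(sprintf("<custom_hierarchy> %d selected regions, %d labels (%d unmapped)\n",
              length(x$selected_ids), length(x$leaf_map), length(x$unmapped)))
  invisible(x)
}

#' Map a grid of atlas labels to custom-hierarchy IDs
#'
#' @param hierarchy a [collapse_to_custom()] result.
#' @param ids integer vector/matrix of atlas labels (0 = outside, passes
#'   through unchanged).
#' @return same shape as `ids`, values in `{0, -1, selected ids}`.
#' @export
custom_region_of <- function(hierarchy, ids) {
  stopifnot(inherits(hierarchy, "custom_hierarchy"))
  out <- ids
  nz <- which(ids != 0L)
  if (length(nz)) {
    m <- match(as.character(ids[nz]), names(hierarchy$leaf_map))
    if (anyNA(m)) {
      stop("labels not covered by the hierarchy leaf_map", call. = FALSE)
    }
    out[nz] <- hierarchy$leaf_map[m]
  }
  out
}

#' Export / import a custom hierarchy as TXT
#'
#' TSV dialect: header `custom_name<TAB>custom_id<TAB>member_ids` with
#' semicolon-separated atlas label IDs per row; unmapped labels are carried on
#' an explicit `UNMAPPED` row with `custom_id` -1. Re-import reproduces the
#' leaf map exactly.
#'
#' @param hierarchy a [collapse_to_custom()] result.
#' @param path output TXT/TSV path.
#' @export
export_custom_hierarchy <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "custom_hierarchy"))
  rows <- lapply(hierarchy$selected_ids, function(sid) {
    members <- names(hierarchy$leaf_map)[hierarchy$leaf_map == sid]
    list(custom_name = unname(hierarchy$names[[as.character(sid)]]),
         custom_id = sid,
         member_ids = paste(members, collapse = ";"))
  })
  if (length(hierarchy$unmapped)) {
    rows <- c(rows, list(list(
      custom_name = "UNMAPPED", custom_id = -1L,
      member_ids = paste(hierarchy$unmapped, collapse = ";"))))
  }
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname export_custom_hierarchy
#' @export
read_custom_hierarchy <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("custom_name", "member_ids"), integer = "custom_id"))
  leaf_map <- integer()
  nms <- character()
  for (i in seq_len(nrow(dt))) {
    members <- strsplit(dt$member_ids[i], ";", fixed = TRUE)[[1]]
    members <- members[nzchar(members)]
    add <- rep(dt$custom_id[i], length(members))
    names(add) <- members
    leaf_map <- c(leaf_map, add)
    if (dt$custom_id[i] != -1L) nms[as.character(dt$custom_id[i])] <-
        dt$custom_name[i]
  }
  sel <- dt$custom_id[dt$custom_id != -1L]
  structure(
    list(selected_ids = sel, leaf_map = leaf_map, names = nms,
         unmapped = as.integer(names(leaf_map)[leaf_map == -1L])),
    class = "custom_hierarchy"
  )
}

#' Hemisphere mask over an atlas volume
#'
#' Hemibrain sections require excluding the missing hemisphere from
#' quantification. The mask is defined along the volume's declared
#' medio-lateral axis using voxel-center coordinates (voxel `i`, 0-based, sits
#' at coordinate `i`): `left` keeps coordinates strictly below
#' `midline_voxel`, `right` keeps the rest (half-open split), `both` keeps
#' everything. Left and right masks therefore partition the volume for any
#' midline.
#'
#' @param volume an [atlas_volume()].
#' @param side one of `"left"`, `"right"`, `"both"`.
#' @param midline_voxel split coordinate along the medio-lateral axis, in
#'   voxel units within `[0, extent]`.
#' @return object of class `hemisphere_mask` with a logical `mask` array
#'   shaped like the volume.
#' @export
make_hemisphere_mask <- function(volume, side = c("left", "right", "both"),
                                 midline_voxel = NULL) {
  stopifnot(inherits(volume, "atlas_volume"))
  side <- match.arg(side)
  shape <- volume$shape
  if (side == "both") {
    mask <- array(TRUE, dim = shape)
  } else {
    if (is.null(midline_voxel)) {
      stop("`midline_voxel` required for one-sided masks", call. = FALSE)
    }
    extent <- shape[volume$ml_axis]
    if (midline_voxel < 0 || midline_voxel > extent) {
      stop("`midline_voxel` outside the axis extent", call. = FALSE)
    }
    coord <- seq_len(extent) - 1  # voxel-center coordinates
    keep <- if (side == "left") coord < midline_voxel else coord >= midline_voxel
    mask <- array(FALSE, dim = shape)
    idx <- vector("list", 3L)
    for (a in 1:3) idx[[a]] <- seq_len(shape[a])
    idx[[volume$ml_axis]] <- which(keep)
    mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  }
  structure(
    list(side = side, midline_voxel = midline_voxel, mask = mask),
    class = "hemisphere_mask"
  )
}
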