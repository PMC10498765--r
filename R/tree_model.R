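#' Vessel segment
#'
#' A segment is one branch of the epicardial coronary tree: a tube of given
#' centerline length with lumen diameters at its proximal and distal ends,
#' optionally refined by an ordered diameter profile along the arc. All
#' geometry is stored in SI units (metres).
#'
#' @param id segment identifier (character).
#' @param length centerline length, metres.
#' @param d_prox,d_dist lumen diameters at the proximal and distal ends,
#'   metres.
#' @param parent identifier of the parent segment, or `NA` for the root.
#' @param profile optional data frame with columns `pos` (arc position in
#'   `[0, length]`, strictly increasing, first 0, last `length`) and
#'   `diameter` (metres). Diameters between profile points are linearly
#'   interpolated.
#' @return an object of class `vessel_segment`.
#' @export
#' @examples
#' segment("LAD", length = 0.03, d_prox = 0.003, d_dist = 0.0025)
segment <- function(id, length, d_prox, d_dist, parent = NA_character_,
                    profile = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.null(profile)) {
    profile <- as.data.frame(profile)
    if (!all(c("pos", "diameter") %in% names(profile)))
      stop("profile must have columns 'pos' and 'diameter'", call. = FALSE)
    profile <- profile[c("pos", "diameter")]
  }
  structure(
    list(id = id, length = as.numeric(length),
         d_prox = as.numeric(d_prox), d_dist = as.numeric(d_dist),
         parent = if (is.na(parent)) NA_character_ else as.character(parent),
         profile = profile),
    class = "vessel_segment")
}

#' Stenosis annotation
#'
#' A stenosis is an explicit annotation on a segment: over the lesion span
#' the lumen diameter is overridden to `ref_diameter * (1 - severity)`.
#' Keeping lesions as annotations (rather than baking them into the
#' geometry) makes severity sweeps scriptable.
#'
#' @param segment id of the segment carrying the lesion.
#' @param start arc position of the proximal lesion shoulder, metres.
#' @param length lesion length, metres.
#' @param severity fractional diameter reduction, in (0, 1).
#' @param ref_diameter healthy reference diameter at the lesion, metres.
#' @return a one-row data frame of class `stenosis`.
#' @export
stenosis <- function(segment, start, length, severity, ref_diameter) {
  structure(
    data.frame(segment = as.character(segment), start = as.numeric(start),
               length = as.numeric(length), severity = as.numeric(severity),
               ref_diameter = as.numeric(ref_diameter),
               stringsAsFactors = FALSE),
    class = c("stenosis", "data.frame"))
}

.empty_stenoses <- function() {
  data.frame(segment = character(), start = numeric(), length = numeric(),
             severity = numeric(), ref_diameter = numeric(),
             stringsAsFactors = FALSE)
}

#' Coronary tree
#'
#' Assembles segments (and optional stenosis annotations) into a rooted
#' directed tree with one inlet and one or more outlets (the leaves).
#' Structural defects -- duplicate ids, unknown parents, zero or multiple
#' roots, cycles -- are errors; value-level invariant violations are
#' reported by [validate_tree()].
#'
#' @param segments a list of [segment()] objects.
#' @param stenoses optional data frame of [stenosis()] rows.
#' @param name optional tree name stored in metadata.
#' @return an object of class `coronary_tree` with elements `segments`
#'   (named list), `stenoses` (data frame), `root`, `outlets`, `children`
#'   (named list of child id vectors) and `metadata`.
#' @export
coronary_tree <- function(segments, stenoses = NULL, name = NULL) {
  ids <- vapply(segments, function(s) s$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate segment id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(segments) <- ids
  parents <- vapply(segments, function(s) s$parent %||% NA_character_,
                    character(1))
  is_root <- is.na(parents)
  if (sum(is_root) != 1L)
    stop("tree must have exactly one root, found ", sum(is_root),
         call. = FALSE)
  unknown <- setdiff(parents[!is_root], ids)
  if (length(unknown))
    stop("unknown parent id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  root <- ids[is_root]
  children <- lapply(ids, function(i) unname(ids[!is_root & parents == i]))
  names(children) <- ids
  # cycle check: every id must reach the root
  for (i in ids) {
    seen <- character()
    cur <- i
    while (!is.na(cur)) {
      if (cur %in% seen)
        stop("cycle detected through segment '", i, "'", call. = FALSE)
      seen <- c(seen, cur)
      cur <- segments[[cur]]$parent
    }
  }
  if (is.null(stenoses) || nrow(stenoses) == 0L) {
    stenoses <- .empty_stenoses()
  } else {
    stenoses <- as.data.frame(stenoses)[names(.empty_stenoses())]
    bad <- setdiff(stenoses$segment, ids)
    if (length(bad))
      stop("stenosis references unknown segment: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  outlets <- ids[vapply(children, function(ch) length(ch) == 0L, logical(1))]
  structure(
    list(segments = segments, stenoses = stenoses, root = root,
         outlets = sort(outlets), children = children,
         metadata = list(name = name, schema = "ffru-tree/1")),
    class = "coronary_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coronary_tree <- function(x, ...) {
  cat("<coronary_tree>", x$metadata$name %||% "", "\n")
  cat("  segments:", length(x$segments),
      " outlets:", length(x$outlets),
      " stenoses:", nrow(x$stenoses), "\n")
  cat("  root:", x$root, "\n")
  invisible(x)
}

#' Validate a coronary tree
#'
#' Checks the value-level invariants of every segment and stenosis and
#' returns a character vector of violations (empty when the tree is valid).
#' Each violation names the offending segment and the rule broken.
#' Structural invariants (single root, acyclicity) are enforced at
#' construction and cannot be violated here.
#'
#' @param tree a [coronary_tree()].
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validate_tree <- function(tree) {
  v <- character()
  for (s in tree$segments) {
    if (!is.finite(s$length) || s$length <= 0)
      v <- c(v, sprintf("segment '%s': length must be > 0", s$id))
    if (!is.finite(s$d_prox) || s$d_prox <= 0)
      v <- c(v, sprintf("segment '%s': d_prox must be > 0", s$id))
    if (!is.finite(s$d_dist) || s$d_dist <= 0)
      v <- c(v, sprintf("segment '%s': d_dist must be > 0", s$id))
    if (!is.null(s$profile)) {
      p <- s$profile
      if (any(p$diameter <= 0))
        v <- c(v, sprintf("segment '%s': profile diameters must be > 0", s$id))
      if (nrow(p) < 2L || any(diff(p$pos) <= 0))
        v <- c(v, sprintf(
          "segment '%s': profile positions must be strictly increasing", s$id))
      else {
        if (abs(p$pos[1L]) > 1e-12)
          v <- c(v, sprintf("segment '%s': profile must start at 0", s$id))
        if (abs(p$pos[nrow(p)] - s$length) > 1e-12 * max(1, s$length))
          v <- c(v, sprintf("segment '%s': profile must end at L", s$id))
        if (abs(p$diameter[1L] - s$d_prox) > 1e-12)
          v <- c(v, sprintf(
            "segment '%s': profile start diameter inconsistent with d_prox",
            s$id))
        if (abs(p$diameter[nrow(p)] - s$d_dist) > 1e-12)
          v <- c(v, sprintf(
            "segment '%s': profile end diameter inconsistent with d_dist",
            s$id))
      }
    }
  }
  if (nrow(tree$stenoses)) {
    for (k in seq_len(nrow(tree$stenoses))) {
      st <- tree$stenoses[k, ]
      seg <- tree$segments[[st$segment]]
      if (!(st$severity > 0 && st$severity < 1))
        v <- c(v, sprintf(
          "stenosis on '%s': severity must be in (0, 1), got %g",
          st$segment, st$severity))
      if (st$length <= 0)
        v <- c(v, sprintf("stenosis on '%s': lesion length must be > 0",
                          st$segment))
      if (st$ref_diameter <= 0)
        v <- c(v, sprintf("stenosis on '%s': ref_diameter must be > 0",
                          st$segment))
      if (st$start < 0 || st$start + st$length > seg$length + 1e-12)
        v <- c(v, sprintf(
          "stenosis on '%s': lesion [%g, %g] exceeds segment length %g",
          st$segment, st$start, st$start + st$length, seg$length))
    }
  }
  v
}

#' Mean cross-sectional area of a segment
#'
#' The representative lumen area of a branch is the arithmetic mean of the
#' end areas, `A = (A_inlet + A_outlet) / 2` with `A = pi d^2 / 4` at each
#' end. Any interior diameter profile is deliberately ignored here; profiles
#' enter only the piecewise resistance integration.
#'
#' @param seg a [segment()].
#' @return area in m^2.
#' @export
#' @examples
#' segment_mean_area(segment("s", 0.01, 0.003, 0.003))  # 7.0686e-6 m^2
segment_mean_area <- function(seg) {
  (pi * seg$d_prox^2 / 4 + pi * seg$d_dist^2 / 4) / 2
}

#' Path from the root to a node
#'
#' @param tree a [coronary_tree()].
#' @param node a segment id.
#' @return character vector of segment ids, root first, `node` last.
#' @export
path_to_root <- function(tree, node) {
  if (!node %in% names(tree$segments))
    stop("unknown segment id: '", node, "'", call. = FALSE)
  path <- character()
  cur <- node
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- tree$segments[[cur]]$parent
  }
  path
}

#' Outlets downstream of a segment
#'
#' @param tree a [coronary_tree()].
#' @param node a segment id.
#' @return ids of the terminal segments in the subtree rooted at `node`
#'   (`node` itself if it is a leaf).
#' @export
descendant_outlets <- function(tree, node) {
  ch <- tree$children[[node]]
  if (length(ch) == 0L) return(node)
  sort(unlist(lapply(ch, descendant_outlets, tree = tree), use.names = FALSE))
}

# Piecewise-linear diameter profile of a segment as an interval table,
# optionally overridden by stenosis annotations (lesion spans get the
# constant diameter ref_diameter * (1 - severity); overlapping lesions take
# the narrowest lumen). Returns data.frame(x0, x1, d0, d1).
segment_intervals <- function(seg, stenoses = NULL) {
  base <- seg$profile
  if (is.null(base))
    base <- data.frame(pos = c(0, seg$length),
                       diameter = c(seg$d_prox, seg$d_dist))
  st <- NULL
  if (!is.null(stenoses) && nrow(stenoses)) {
    st <- stenoses[stenoses$segment == seg$id, , drop = FALSE]
    if (nrow(st) == 0L) st <- NULL
  }
  brk <- base$pos
  if (!is.null(st))
    brk <- c(brk, st$start, pmin(st$start + st$length, seg$length))
  brk <- sort(unique(pmin(pmax(brk, 0), seg$length)))
  healthy <- function(x) stats::approx(base$pos, base$diameter, x,
                                       rule = 2)$y
  x0 <- brk[-length(brk)]
  x1 <- brk[-1L]
  d0 <- healthy(x0)
  d1 <- healthy(x1)
  if (!is.null(st)) {
    for (k in seq_len(nrow(st))) {
      dl <- st$ref_diameter[k] * (1 - st$severity[k])
      inside <- x0 >= st$start[k] - 1e-15 &
        x1 <= st$start[k] + st$length[k] + 1e-15
      d0[inside] <- pmin(d0[inside], dl)
      d1[inside] <- pmin(d1[inside], dl)
    }
  }
  data.frame(x0 = x0, x1 = x1, d0 = d0, d1 = d1)
}

# ---- file I/O -------------------------------------------------------------

#' Read a coronary tree from disk
#'
#' Two on-disk dialects are supported (documented in
#' `system.file("extdata", "tree-schema.md", package = "ffrnet")`):
#'
#' * a JSON document (schema `ffru-tree/1`) with top-level keys `units`,
#'   `segments` and `stenoses`;
#' * a two-file CSV dialect: a segments table (`id, parent, length, d_prox,
#'   d_dist`) plus an optional stenoses table (`segment, start, length,
#'   severity, ref_diameter`), with lengths in the unit given by `units`.
#'
#' Whatever the declared file unit (mm, cm or m), the returned tree is in
#' SI metres.
#'
#' @param path path to the JSON file, or to the segments CSV.
#' @param stenoses_path optional path to the stenoses CSV (CSV dialect only).
#' @param units length unit for the CSV dialect (`"mm"`, `"cm"` or `"m"`);
#'   the JSON dialect declares its unit in the file.
#' @return a validated [coronary_tree()].
#' @export
load_tree <- function(path, stenoses_path = NULL, units = "mm") {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    .load_tree_json(path)
  } else {
    .load_tree_csv(path, stenoses_path, units)
  }
}

.load_tree_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$segments))
    stop("tree JSON: missing required field 'segments'", call. = FALSE)
  f <- .length_factor((doc$units %||% list())$length %||% "m")
  segs <- lapply(doc$segments, function(s) {
    for (fld in c("id", "length", "d_prox", "d_dist"))
      if (is.null(s[[fld]]))
        stop("tree JSON: segment missing required field '", fld, "'",
             call. = FALSE)
    prof <- NULL
    if (!is.null(s$profile)) {
      m <- do.call(rbind, lapply(s$profile, unlist))
      prof <- data.frame(pos = m[, 1] * f, diameter = m[, 2] * f)
    }
    segment(s$id, s$length * f, s$d_prox * f, s$d_dist * f,
            parent = s$parent %||% NA_character_, profile = prof)
  })
  st <- NULL
  if (length(doc$stenoses)) {
    st <- do.call(rbind, lapply(doc$stenoses, function(x) {
      for (fld in c("segment", "start", "length", "severity", "ref_diameter"))
        if (is.null(x[[fld]]))
          stop("tree JSON: stenosis missing required field '", fld, "'",
               call. = FALSE)
      stenosis(x$segment, x$start * f, x$length * f, x$severity,
               x$ref_diameter * f)
    }))
  }
  tree <- coronary_tree(segs, st, name = (doc$metadata %||% list())$name)
  .assert_valid(tree)
}

.load_tree_csv <- function(path, stenoses_path, units) {
  f <- .length_factor(units)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "parent", "length", "d_prox", "d_dist")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("segments CSV: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  segs <- lapply(seq_len(nrow(tab)), function(k) {
    p <- tab$parent[k]
    if (is.na(p) || p == "") p <- NA_character_
    segment(as.character(tab$id[k]), tab$length[k] * f, tab$d_prox[k] * f,
            tab$d_dist[k] * f, parent = p)
  })
  st <- NULL
  if (!is.null(stenoses_path)) {
    stab <- utils::read.csv(stenoses_path, stringsAsFactors = FALSE)
    need <- c("segment", "start", "length", "severity", "ref_diameter")
    miss <- setdiff(need, names(stab))
    if (length(miss))
      stop("stenoses CSV: missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (nrow(stab))
      st <- do.call(rbind, lapply(seq_len(nrow(stab)), function(k)
        stenosis(as.character(stab$segment[k]), stab$start[k] * f,
                 stab$length[k] * f, stab$severity[k],
                 stab$ref_diameter[k] * f)))
  }
  .assert_valid(coronary_tree(segs, st))
}

.assert_valid <- function(tree) {
  v <- validate_tree(tree)
  if (length(v))
    stop("invalid tree:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  tree
}

#' Write a coronary tree to JSON
#'
#' Emits the `ffru-tree/1` JSON schema. Geometry is written in the requested
#' unit at full double precision, so `load_tree(write_tree(tree))` round
#' trips exactly.
#'
#' @param tree a [coronary_tree()].
#' @param path output path.
#' @param units length unit to declare and write (`"mm"`, `"cm"` or `"m"`).
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, units = "m") {
  f <- .length_factor(units)
  segs <- lapply(unname(tree$segments), function(s) {
    out <- list(id = s$id, parent = s$parent, length = s$length / f,
                d_prox = s$d_prox / f, d_dist = s$d_dist / f)
    if (is.na(s$parent)) out$parent <- NULL
    if (!is.null(s$profile))
      out$profile <- lapply(seq_len(nrow(s$profile)), function(k)
        c(s$profile$pos[k] / f, s$profile$diameter[k] / f))
    out
  })
  st <- lapply(seq_len(nrow(tree$stenoses)), function(k) {
    x <- tree$stenoses[k, ]
    list(segment = x$segment, start = x$start / f, length = x$length / f,
         severity = x$severity, ref_diameter = x$ref_diameter / f)
  })
  doc <- list(schema = "ffru-tree/1", units = list(length = units),
              root = tree$root, segments = segs, stenoses = st,
              metadata = list(name = tree$metadata$name))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
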