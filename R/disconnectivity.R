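# Superbasin analysis and disconnectivity graphs.

#' Build a disconnectivity tree
#'
#' At each threshold of a uniform energy grid, superbasins are the connected
#' components of the subgraph joining minima through transition states below
#' the threshold (union-find); the tree records how basins merge between
#' consecutive levels. Works on potential energies of a `ktn` or on the free
#' energies of a `regrouped_network` (whose groups become the leaves).
#'
#' @param x A `ktn` or `regrouped_network`.
#' @param n_levels Number of uniform threshold levels (>= 2).
#' @param energy_key `"potential"` or `"free"` (free requires a
#'   `regrouped_network`).
#' @param levels Optional explicit threshold vector (overrides `n_levels`).
#' @return A `disconnectivity_tree`: `levels`, `roots` (recursive node lists
#'   with `members`, `level`, `children`), `leaf_energies`, `n_basins`
#'   (basins per level).
#' @export
build_disconnectivity_tree <- function(x, n_levels = 50L,
                                       energy_key = c("potential", "free"),
                                       levels = NULL) {
  energy_key <- match.arg(energy_key)
  if (inherits(x, "regrouped_network")) {
    if (energy_key == "free") {
      node_e <- x$group_free_energies
      ids <- as.integer(names(node_e))
      ed <- data.frame(m1 = x$inter_group_ts$g1, m2 = x$inter_group_ts$g2,
                       energy = x$inter_group_ts$ts_F)
    } else {
      # regrouping at threshold 0 reduces to the raw network
      db <- x$db
      node_e <- db$min_energies
      ids <- ktn_min_ids(db)
      ed <- ktn_edges(db)
    }
  } else {
    if (energy_key == "free")
      stop("free-energy trees need a regrouped_network")
    node_e <- x$min_energies
    ids <- ktn_min_ids(x)
    ed <- ktn_edges(x)
  }
  if (!length(ids)) stop("empty database")
  node_e <- setNames(as.numeric(node_e), names(node_e))
  ed <- ed[ed$m1 != ed$m2, , drop = FALSE]
  if (is.null(levels)) {
    if (n_levels < 2) stop("n_levels must be >= 2")
    lo <- min(node_e)
    hi <- if (nrow(ed)) max(ed$energy) else lo + 1
    levels <- seq(lo, hi, length.out = n_levels + 1L)[-1]
  }
  levels <- sort(levels)
  L <- length(levels)
  # membership per level
  basins <- vector("list", L)
  for (l in seq_len(L)) {
    present <- ids[node_e[as.character(ids)] <= levels[l]]
    sub <- ed[ed$energy <= levels[l] &
                ed$m1 %in% present & ed$m2 %in% present, , drop = FALSE]
    g <- igraph::make_empty_graph(n = length(present), directed = FALSE)
    igraph::V(g)$name <- as.character(present)
    if (nrow(sub))
      g <- igraph::add_edges(g, rbind(as.character(sub$m1),
                                      as.character(sub$m2)))
    comp <- igraph::components(g)$membership
    basins[[l]] <- split(present, comp[as.character(present)])
  }
  make_node <- function(l, members) {
    if (length(members) == 1)
      return(list(level = l, members = members, children = list(),
                  leaf = members))
    if (l == 1) {
      kids <- lapply(sort(members), function(m)
        list(level = 1L, members = m, children = list(), leaf = m))
      return(list(level = 1L, members = members, children = kids,
                  leaf = NA_integer_))
    }
    below <- basins[[l - 1]]
    sub <- below[vapply(below, function(b) any(b %in% members), logical(1))]
    stray <- setdiff(members, unlist(sub))   # minima above level l-1
    kids <- c(lapply(sub, function(b) make_node(l - 1, b)),
              lapply(stray, function(m)
                list(level = l, members = m, children = list(), leaf = m)))
    # deterministic child order: subtree size descending, then smallest id
    ord <- order(-vapply(kids, function(k) length(k$members), numeric(1)),
                 vapply(kids, function(k) min(k$members), numeric(1)))
    list(level = l, members = members, children = kids[ord],
         leaf = NA_integer_)
  }
  roots <- lapply(basins[[L]], function(b) make_node(L, b))
  ord <- order(-vapply(roots, function(k) length(k$members), numeric(1)),
               vapply(roots, function(k) min(k$members), numeric(1)))
  tree <- list(levels = levels, roots = roots[ord],
               leaf_energies = node_e,
               n_basins = vapply(basins, length, integer(1)))
  class(tree) <- "disconnectivity_tree"
  tree
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  cat("<disconnectivity_tree>", length(x$leaf_energies), "leaves,",
      length(x$levels), "levels,", length(x$roots), "root(s)\n")
  invisible(x)
}

#' Indented text serialisation of a disconnectivity tree
#' @param tree A `disconnectivity_tree`.
#' @return Character vector, one node per line (diff-friendly).
#' @export
tree_text <- function(tree) {
  out <- character(0)
  walk <- function(node, depth) {
    lab <- if (!is.na(node$leaf))
      paste0("leaf ", node$leaf, " E=", signif(
        tree$leaf_energies[as.character(node$leaf)], 8))
    else paste0("basin@", signif(tree$levels[node$level], 8), " {",
                paste(sort(node$members), collapse = ","), "}")
    out <<- c(out, paste0(strrep("  ", depth), lab))
    for (k in node$children) walk(k, depth + 1)
  }
  for (r in tree$roots) walk(r, 0)
  out
}

#' Render a disconnectivity tree to SVG
#'
#' Vertical axis is energy; branch x positions come from recursive
#' proportional allocation by subtree leaf count (children ordered by size
#' then id), so the layout is deterministic. Leaf stems are coloured by the
#' order-parameter values in `color_map` (a colour-bar legend is included);
#' leaves missing from the map are drawn grey.
#'
#' @param tree A `disconnectivity_tree`.
#' @param color_map Named numeric vector minimum-id -> value (e.g. helicity).
#' @param out Output SVG path.
#' @param width,height Canvas size in px.
#' @param color_label Legend title.
#' @return `out`, invisibly.
#' @export
render_tree <- function(tree, color_map = NULL, out = "tree.svg",
                        width = 600, height = 700, color_label = "order") {
  margin <- 50
  e_lo <- min(tree$leaf_energies)
  e_hi <- max(tree$levels)
  yof <- function(e) margin + (e_hi - e) / (e_hi - e_lo) * (height - 2 * margin)
  # leaf positions by DFS
  n_leaves <- length(tree$leaf_energies)
  leaf_x <- new.env(parent = emptyenv())
  counter <- 0
  assign_x <- function(node) {
    if (!is.na(node$leaf)) {
      counter <<- counter + 1
      assign(as.character(node$leaf), counter, envir = leaf_x)
      return(counter)
    }
    mean(vapply(node$children, assign_x, numeric(1)))
  }
  for (r in tree$roots) assign_x(r)
  xof <- function(i) margin + i / (counter + 1) * (width - 2 * margin - 60)
  val_range <- if (length(color_map)) range(color_map, na.rm = TRUE) else c(0, 1)
  col_of <- function(m) {
    v <- if (!is.null(color_map)) color_map[as.character(m)] else NA
    if (is.na(v)) return("#999999")
    t <- if (diff(val_range) > 0) (v - val_range[1]) / diff(val_range) else 0.5
    rgb(t, 0.2, 1 - t)
  }
  segs <- character(0)
  seg <- function(x1, y1, x2, y2, col = "#222222") {
    segs <<- c(segs, sprintf(
      '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-width="1.4"/>',
      x1, y1, x2, y2, col))
  }
  node_x <- function(node) {
    if (!is.na(node$leaf)) return(xof(get(as.character(node$leaf),
                                          envir = leaf_x)))
    mean(vapply(node$children, node_x, numeric(1)))
  }
  walk <- function(node, y_top) {
    x <- node_x(node)
    if (!is.na(node$leaf)) {
      y_leaf <- yof(tree$leaf_energies[as.character(node$leaf)])
      seg(x, y_top, x, y_leaf, col_of(node$leaf))
      return(invisible())
    }
    y_here <- yof(tree$levels[node$level])
    seg(x, y_top, x, y_here)
    kx <- vapply(node$children, node_x, numeric(1))
    seg(min(kx), y_here, max(kx), y_here)
    for (k in node$children) walk(k, y_here)
  }
  for (r in tree$roots) walk(r, yof(tree$levels[r$level]) - 10)
  # energy axis ticks
  ticks <- pretty(c(e_lo, e_hi), 6)
  axis_svg <- unlist(lapply(ticks[ticks >= e_lo & ticks <= e_hi], function(t)
    c(sprintf('<line x1="%.1f" y1="%.2f" x2="%.1f" y2="%.2f" stroke="#555"/>',
              width - 55, yof(t), width - 50, yof(t)),
      sprintf('<text x="%.1f" y="%.2f" font-size="10" fill="#333">%s</text>',
              width - 47, yof(t) + 3, signif(t, 4)))))
  # colour bar legend
  leg <- character(0)
  if (!is.null(color_map)) {
    for (i in 0:19) {
      t <- i / 19
      leg <- c(leg, sprintf(
        '<rect x="%.1f" y="%.2f" width="10" height="%.2f" fill="%s"/>',
        width - 30, margin + (1 - t) * 100, 100 / 20, rgb(t, 0.2, 1 - t)))
    }
    leg <- c(leg,
      sprintf('<text x="%.1f" y="%.1f" font-size="10" fill="#333">%s</text>',
              width - 40, margin - 6, color_label),
      sprintf('<text x="%.1f" y="%.1f" font-size="9" fill="#333">%.3g</text>',
              width - 18, margin + 104, val_range[1]),
      sprintf('<text x="%.1f" y="%.1f" font-size="9" fill="#333">%.3g</text>',
              width - 18, margin + 8, val_range[2]))
  }
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   width, height),
           '<rect width="100%" height="100%" fill="white"/>',
           segs, axis_svg, leg, "</svg>")
  writeLines(svg, out)
  invisible(out)
}

#' @importFrom grDevices rgb
NULL
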