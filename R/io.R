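# Text persistence: PATHSAMPLE-style min.data / ts.data plus an extended-XYZ
# coordinate archive, all whitespace-separated plain text.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a stationary-point database
#'
#' `write_db()` persists a `ktn` into a directory of text files:
#' `min.data` (energy, log-product of frequencies, 1, 0, 0, 0 per line, in id
#' order), `ts.data` (energy, log-product, 1, min1, min2, 0, 0, 0),
#' `min.xyz` / `ts.xyz` (extended XYZ frames keyed `id=N`, present when
#' records carry coordinates), `info.txt` (dimension and surface label) and
#' optionally `min.order.tsv` with cached order parameters. Energies are
#' written with 17 significant digits so the round-trip is lossless.
#'
#' @param db A `ktn`.
#' @param path Directory (created if absent).
#' @return `read_db()` returns the reconstructed `ktn`; `write_db()` the path.
#' @export
write_db <- function(db, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  mids <- ktn_min_ids(db)
  mlines <- vapply(mids, function(id) {
    m <- ktn_minimum(db, id)
    paste(fmt17(m$energy), fmt17(m$log_product_frequencies), "1 0 0 0")
  }, character(1))
  writeLines(mlines, file.path(path, "min.data"))
  tids <- as.integer(names(db$ts_energies))
  tlines <- vapply(tids, function(id) {
    t <- ktn_ts(db, id)
    paste(fmt17(t$energy), fmt17(t$log_product_frequencies), "1",
          t$min_minus, t$min_plus, "0 0 0")
  }, character(1))
  writeLines(tlines, file.path(path, "ts.data"))
  dim <- NA_integer_
  write_xyz_archive <- function(ids, get, file) {
    frames <- character(0)
    for (id in ids) {
      rec <- get(id)
      if (is.null(rec$coords)) next
      X <- coords_matrix(rec$coords, guess_dim(rec$coords))
      dim <<- ncol(X)
      Xp <- cbind(X, matrix(0, nrow(X), 3 - ncol(X)))
      frames <- c(frames, nrow(X), paste0("id=", id),
                  apply(Xp, 1, function(r) paste("X", paste(fmt17(r), collapse = " "))))
    }
    if (length(frames)) writeLines(frames, file.path(path, file))
  }
  write_xyz_archive(mids, function(i) ktn_minimum(db, i), "min.xyz")
  write_xyz_archive(tids, function(i) ktn_ts(db, i), "ts.xyz")
  writeLines(c(paste("surface", db$surface_name),
               paste("dim", dim),
               paste("min_ids", paste(mids, collapse = " ")),
               paste("ts_ids", paste(tids, collapse = " "))),
             file.path(path, "info.txt"))
  op <- lapply(mids, function(id) ktn_minimum(db, id)$order_parameters)
  keys <- unique(unlist(lapply(op, names)))
  if (length(keys)) {
    tab <- data.frame(id = mids)
    for (k in keys)
      tab[[k]] <- vapply(op, function(o) o[[k]] %||% NA_real_, numeric(1))
    utils::write.table(tab, file.path(path, "min.order.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

guess_dim <- function(coords) {
  n <- length(coords)
  if (n %% 3 == 0) 3L else if (n %% 2 == 0) 2L else 1L
}

#' @rdname write_db
#' @export
read_db <- function(path) {
  info <- readLines(file.path(path, "info.txt"))
  getf <- function(key) {
    ln <- grep(paste0("^", key, " "), info, value = TRUE)
    sub(paste0("^", key, " "), "", ln)
  }
  dim <- suppressWarnings(as.integer(getf("dim")))
  min_ids <- as.integer(strsplit(getf("min_ids"), " +")[[1]])
  ts_ids_str <- getf("ts_ids")
  ts_ids <- if (nzchar(trimws(ts_ids_str)))
    as.integer(strsplit(trimws(ts_ids_str), " +")[[1]]) else integer(0)
  parse_data <- function(file, n_expected, what, line_fields) {
    f <- file.path(path, file)
    lines <- if (file.exists(f)) readLines(f) else character(0)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) != n_expected)
      stop("malformed ", file, ": expected ", n_expected, " records, got ",
           length(lines))
    lapply(seq_along(lines), function(i) {
      toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      if (length(toks) < line_fields)
        stop("malformed ", file, " at line ", i, ": ", length(toks), " fields")
      toks
    })
  }
  coords_map <- function(file) {
    f <- file.path(path, file)
    out <- list()
    if (!file.exists(f)) return(out)
    lines <- readLines(f)
    i <- 1
    while (i <= length(lines)) {
      n <- as.integer(lines[i])
      id <- sub("^id=", "", lines[i + 1])
      block <- lines[(i + 2):(i + 1 + n)]
      xyz <- t(vapply(strsplit(trimws(block), "[[:space:]]+"), function(t)
        as.numeric(t[2:4]), numeric(3)))
      out[[id]] <- as.numeric(t(xyz[, seq_len(if (is.na(dim)) 3L else dim),
                                    drop = FALSE]))
      i <- i + 2 + n
    }
    out
  }
  db <- ktn_new(surface_name = getf("surface"))
  mc <- coords_map("min.xyz")
  md <- parse_data("min.data", length(min_ids), "minima", 2)
  for (k in seq_along(min_ids)) {
    id <- min_ids[k]
    db$minima[[as.character(id)]] <-
      list(id = id, energy = as.numeric(md[[k]][1]),
           coords = mc[[as.character(id)]],
           log_product_frequencies = as.numeric(md[[k]][2]),
           order_parameters = list())
    db$min_energies <- c(db$min_energies,
                         setNames(as.numeric(md[[k]][1]), id))
  }
  db$next_min_id <- if (length(min_ids)) max(min_ids) + 1L else 1L
  tc <- coords_map("ts.xyz")
  td <- parse_data("ts.data", length(ts_ids), "transition states", 5)
  for (k in seq_along(ts_ids)) {
    id <- ts_ids[k]
    m1 <- as.integer(td[[k]][4]); m2 <- as.integer(td[[k]][5])
    db$ts[[as.character(id)]] <-
      list(id = id, energy = as.numeric(td[[k]][1]),
           coords = tc[[as.character(id)]],
           log_product_frequencies = as.numeric(td[[k]][2]),
           min_minus = m1, min_plus = m2, degenerate = m1 == m2)
    db$ts_energies <- c(db$ts_energies,
                        setNames(as.numeric(td[[k]][1]), id))
  }
  db$next_ts_id <- if (length(ts_ids)) max(ts_ids) + 1L else 1L
  op_file <- file.path(path, "min.order.tsv")
  if (file.exists(op_file)) {
    tab <- utils::read.table(op_file, header = TRUE, sep = "\t")
    for (r in seq_len(nrow(tab))) {
      id <- as.character(tab$id[r])
      vals <- as.list(tab[r, setdiff(names(tab), "id"), drop = FALSE])
      db$minima[[id]]$order_parameters <- vals[!is.na(unlist(vals))]
    }
  }
  db
}

# ------------------------------------------------------------ extended XYZ

#' Read / write multi-frame extended XYZ
#'
#' Element column is the bead type; the comment line is free text (energies,
#' ids). `read_xyz()` returns a list of frames, each with `types`, `comment`
#' and flat `coords`.
#'
#' @param frames List of frames: each a list with `coords` (flat numeric),
#'   `types` (character vector, recycled) and optional `comment`.
#' @param path File path.
#' @export
write_xyz <- function(frames, path) {
  out <- character(0)
  for (fr in frames) {
    X <- coords_matrix(fr$coords, 3L)
    types <- rep_len(fr$types %||% "X", nrow(X))
    out <- c(out, nrow(X), fr$comment %||% "",
             paste(types, apply(X, 1, function(r)
               paste(fmt17(r), collapse = " "))))
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop("malformed XYZ at line ", i)
    block <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "[[:space:]]+")
    types <- vapply(block, `[`, character(1), 1)
    xyz <- t(vapply(block, function(t) as.numeric(t[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <-
      list(types = types, comment = lines[i + 1], coords = as.numeric(t(xyz)))
    i <- i + 2 + n
  }
  frames
}

#' Read a key-value configuration file selecting a surface
#'
#' Plain `key value` lines (`#` comments). The `surface` key selects the
#' family; remaining keys are passed as that family's parameters.
#'
#' @param path Config file.
#' @return A `potential_surface`.
#' @export
read_surface_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[[:space:]]+")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- lapply(kv, function(t) {
    v <- paste(t[-1], collapse = " ")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- keys
  fam <- vals$surface
  if (is.null(fam)) stop("config must contain a 'surface' key")
  build_surface(fam, vals[setdiff(keys, "surface")])
}
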