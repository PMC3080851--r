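# JSON network interchange and CSV trajectory files.

#' Write / read a network as JSON
#'
#' The interchange schema has top-level `nodes`, `springs`, `faces`, `cells`
#' and `meta` objects with explicit 0-based ids; coordinates are arrays of
#' three doubles. Round-tripping preserves topology and positions exactly at
#' the printed precision (17 significant digits).
#'
#' @param network a `spring_network`.
#' @param path file path.
#' @return `write_network_json` returns `path` invisibly; `read_network_json`
#'   returns a `spring_network`.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "spring_network"))
  nd <- network$nodes; sp <- network$springs; fc <- network$faces
  obj <- list(
    schema = "alveonet-network/1",
    meta = network$meta[c("lattice", "dims", "cell_size", "prestrain", "v0")],
    params = unclass(network$params),
    nodes = list(position = unname(nd$pos), role = nd$role,
                 is_boundary = nd$is_boundary),
    springs = list(from = sp$from - 1L, to = sp$to - 1L, L0 = sp$L0,
                   kind = sp$kind, k = sp$k, broken = sp$broken),
    faces = list(vertices = lapply(fc$vertices, function(v) v - 1L),
                 center = fc$center - 1L,
                 cells = unname(ifelse(is.na(fc$cells), -1L, fc$cells - 1L)),
                 removed = fc$removed, is_boundary = fc$is_boundary),
    cells = list(faces = lapply(network$cells$faces, function(f) f - 1L),
                 sign = network$cells$sign)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  # simplifyMatrix = FALSE: cycles of equal length must stay lists of
  # vectors, not collapse to a matrix
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$schema, "alveonet-network/1"))
    stop("not an alveonet network file")
  params <- do.call(constitutive,
                    obj$params[intersect(names(obj$params),
                                         c("law", "k", "A", "B", "p", "form"))])
  vpos_all <- matrix(unlist(obj$nodes$position), ncol = 3, byrow = TRUE)
  role <- obj$nodes$role
  n_v <- sum(role == "vertex")
  cell_faces0 <- lapply(obj$cells$faces, function(f) as.integer(f) + 1L)
  face_vertices <- lapply(obj$faces$vertices, function(v) as.integer(v) + 1L)
  sign <- obj$cells$sign
  # rebuild per-cell oriented cycles, then reassemble (guarantees identical
  # derived structure) and restore the damage state
  cycles <- lapply(seq_along(cell_faces0), function(ci) {
    lapply(seq_along(cell_faces0[[ci]]), function(k) {
      f <- cell_faces0[[ci]][k]
      v <- face_vertices[[f]]
      if (sign[[ci]][k] > 0) v else rev(v)
    })
  })
  net <- .assemble_network(vpos_all[seq_len(n_v), , drop = FALSE], cycles,
                           obj$meta$lattice, obj$meta$dims,
                           obj$meta$cell_size, params)
  # positions and rest lengths as stored, not re-derived from the (possibly
  # pre-strained, equilibrated) geometry; the derived spring order must
  # match the stored one
  stopifnot(nrow(net$nodes$pos) == nrow(vpos_all),
            identical(net$springs$from, as.integer(obj$springs$from) + 1L),
            identical(net$springs$to, as.integer(obj$springs$to) + 1L))
  net$nodes$pos <- vpos_all
  net$springs$L0 <- as.numeric(obj$springs$L0)
  net$springs$k <- as.numeric(obj$springs$k)
  net$meta$prestrain <- obj$meta$prestrain
  net$meta$v0 <- obj$meta$v0
  net$meta$box <- rbind(apply(vpos_all[net$nodes$is_boundary, , drop = FALSE], 2, min),
                        apply(vpos_all[net$nodes$is_boundary, , drop = FALSE], 2, max))
  removed <- which(as.logical(obj$faces$removed))
  if (length(removed)) net <- remove_faces(net, removed)
  net$meta$needs_equilibration <- FALSE
  net
}

#' Write / read a destruction trajectory
#'
#' One CSV row per step plus a JSON manifest (same path with extension
#' `.json`) holding the policy, seed and lattice metadata needed to
#' reproduce the run.
#'
#' @param trajectory a `destruction_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `destruction_trajectory` (without the final network).
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "destruction_trajectory"))
  write.csv(trajectory$steps, path, row.names = FALSE)
  manifest <- list(schema = "alveonet-trajectory/1",
                   policy = unclass(trajectory$policy),
                   K0 = trajectory$K0,
                   meta = trajectory$meta,
                   version = as.character(utils::packageVersion("alveonet")))
  jsonlite::write_json(manifest, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  steps <- read.csv(path)
  mpath <- paste0(tools::file_path_sans_ext(path), ".json")
  manifest <- if (file.exists(mpath)) jsonlite::read_json(mpath, simplifyVector = TRUE)
  structure(list(steps = steps,
                 policy = manifest$policy, K0 = manifest$K0,
                 meta = manifest$meta, network = NULL),
            class = "destruction_trajectory")
}
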