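#' @useDynLib lepdcm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef vcov residuals simulate predict
#' @importFrom graphics matplot
#' @keywords internal
"_PACKAGE"

#' Canonical region order of the LEP pain network
#'
#' Region labels in the fixed order used for all parameter vectors and
#' adjacency matrices: contralateral primary somatosensory cortex (lS1),
#' bilateral secondary somatosensory cortices (lS2, rS2), bilateral insulae
#' (lIns, rIns), anterior cingulate cortex (ACC) and the hidden thalamic
#' relay (THAL).
#'
#' @export
lep_regions <- c("lS1", "lS2", "rS2", "lIns", "rIns", "ACC", "THAL")

#' Construct a network specification
#'
#' A network is a set of labelled regions (at most some of them hidden,
#' i.e. contributing nothing to the sensors) plus typed directed edges of
#' class forward, backward or lateral, and the set of regions receiving
#' the exogenous stimulus.
#'
#' @param regions data.frame with columns `label` (character),
#'   `observed` (logical) and optionally `x`,`y`,`z` (MNI mm, may be NA).
#' @param edges data.frame with columns `source`, `target` (region
#'   labels), `class` (one of `"forward"`, `"backward"`, `"lateral"`) and
#'   `modulable` (logical; whether the edge may change between blocks).
#' @param input_regions character vector of region labels receiving the
#'   stimulus input.
#' @return An object of class `lep_network`.
#' @seealso [build_study_network()], [validate_network()], [network_matrices()]
#' @export
lep_network <- function(regions, edges, input_regions) {
  regions$label <- as.character(regions$label)
  if (is.null(regions$x)) regions$x <- NA_real_
  if (is.null(regions$y)) regions$y <- NA_real_
  if (is.null(regions$z)) regions$z <- NA_real_
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$class <- as.character(edges$class)
  net <- structure(
    list(regions = regions, edges = edges,
         input_regions = as.character(input_regions)),
    class = "lep_network")
  rep <- validate_network(net)
  if (length(rep) > 0L)
    stop("invalid network: ", paste(rep, collapse = "; "))
  net
}

#' The seven-region LEP study network
#'
#' Builds the fixed thalamo-cortical pain network: forward connections
#' follow the ascending pain pathways (thalamic relay to lS1, lS2, rS2,
#' lIns and rIns; lS1 to lS2; S2 to the ipsilateral insula; insulae to
#' ACC), backward connections run from every region to the hidden
#' thalamic source plus lS2 to lS1, and homologous areas of the two
#' hemispheres are coupled by directed lateral connections (lS2/rS2 and
#' lIns/rIns, both directions). The stimulus enters at the thalamus; all
#' 21 extrinsic connections may be modulated between blocks.
#'
#' @param coordinates optional named list of MNI mm triples per region
#'   label; defaults to NA placeholders (coordinates play no role in the
#'   synthetic gain observation model).
#' @return A `lep_network` with 7 regions (1 hidden) and 21 directed
#'   edges: 10 forward, 7 backward, 4 lateral.
#' @export
build_study_network <- function(coordinates = NULL) {
  regions <- data.frame(label = lep_regions,
                        observed = lep_regions != "THAL",
                        x = NA_real_, y = NA_real_, z = NA_real_)
  if (!is.null(coordinates)) {
    for (lab in names(coordinates)) {
      i <- match(lab, regions$label)
      if (is.na(i)) stop("unknown region in coordinates: ", lab)
      regions[i, c("x", "y", "z")] <- as.numeric(coordinates[[lab]])
    }
  }
  fwd <- rbind(c("THAL", "lS1"), c("THAL", "lS2"), c("THAL", "rS2"),
               c("THAL", "lIns"), c("THAL", "rIns"),
               c("lS1", "lS2"), c("lS2", "lIns"), c("rS2", "rIns"),
               c("lIns", "ACC"), c("rIns", "ACC"))
  bwd <- rbind(c("lS1", "THAL"), c("lS2", "THAL"), c("rS2", "THAL"),
               c("lIns", "THAL"), c("rIns", "THAL"), c("ACC", "THAL"),
               c("lS2", "lS1"))
  lat <- rbind(c("lS2", "rS2"), c("rS2", "lS2"),
               c("lIns", "rIns"), c("rIns", "lIns"))
  edges <- data.frame(
    source = c(fwd[, 1], bwd[, 1], lat[, 1]),
    target = c(fwd[, 2], bwd[, 2], lat[, 2]),
    class = rep(c("forward", "backward", "lateral"),
                c(nrow(fwd), nrow(bwd), nrow(lat))),
    modulable = TRUE)
  lep_network(regions, edges, input_regions = "THAL")
}

#' Validate a network specification
#'
#' Checks structural invariants and returns a character vector of
#' violations; an empty vector means the network is valid. Checked:
#' unique region labels, known edge endpoints, no self edges, no
#' duplicate directed edges, valid edge classes, at least one input
#' region with known label, and modulable edges being actual edges.
#'
#' @param net a `lep_network` (or a bare list with the same fields).
#' @return character vector of human-readable violations (empty iff valid).
#' @export
validate_network <- function(net) {
  out <- character(0)
  labs <- net$regions$label
  if (anyDuplicated(labs))
    out <- c(out, "duplicate region labels")
  e <- net$edges
  bad <- !(e$source %in% labs) | !(e$target %in% labs)
  if (any(bad))
    out <- c(out, paste0("edge with unknown endpoint: ",
                         paste(e$source[bad], e$target[bad], sep = "->",
                               collapse = ", ")))
  self <- e$source == e$target
  if (any(self))
    out <- c(out, paste0("self edge: ", paste(e$source[self], collapse = ", ")))
  key <- paste(e$source, e$target)
  if (anyDuplicated(key))
    out <- c(out, "duplicate directed edge")
  if (!all(e$class %in% c("forward", "backward", "lateral")))
    out <- c(out, "unknown edge class")
  if (length(net$input_regions) < 1L)
    out <- c(out, "no input region")
  if (!all(net$input_regions %in% labs))
    out <- c(out, "unknown input region")
  if ("THAL" %in% labs) {
    obs <- net$regions$observed[match("THAL", labs)]
    if (isTRUE(obs))
      out <- c(out, "hidden-flag violation: THAL marked observed")
  }
  out
}

#' Edge-class adjacency matrices
#'
#' Converts the edge list into three binary region-by-region matrices
#' (forward, backward, lateral) with entry `(target, source) = 1` iff the
#' directed edge source -> target of that class exists. Row/column order
#' is the network's region order (for the study network, [lep_regions]).
#'
#' @param net a `lep_network`.
#' @return named list of three `n x n` 0/1 matrices with dimnames, plus
#'   `modulable`, the 0/1 matrix marking modulable edges across classes.
#' @export
network_matrices <- function(net) {
  labs <- net$regions$label
  n <- length(labs)
  mk <- function() matrix(0, n, n, dimnames = list(labs, labs))
  out <- list(forward = mk(), backward = mk(), lateral = mk(),
              modulable = mk())
  e <- net$edges
  si <- match(e$source, labs)
  ti <- match(e$target, labs)
  if (anyNA(si) || anyNA(ti)) stop("edge with unknown endpoint")
  for (k in seq_len(nrow(e))) {
    out[[e$class[k]]][ti[k], si[k]] <- 1
    if (isTRUE(e$modulable[k])) out$modulable[ti[k], si[k]] <- 1
  }
  out
}

#' Rebuild an edge list from class adjacency matrices
#'
#' Inverse of [network_matrices()]: scans the three class matrices and
#' emits the corresponding edge data.frame in class order
#' (forward, backward, lateral), sources varying fastest within class.
#'
#' @param mats list with `forward`, `backward`, `lateral` (and optionally
#'   `modulable`) matrices as produced by [network_matrices()].
#' @return edge data.frame with columns source, target, class, modulable.
#' @export
edges_from_matrices <- function(mats) {
  labs <- rownames(mats$forward)
  res <- list()
  for (cl in c("forward", "backward", "lateral")) {
    idx <- which(mats[[cl]] != 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
    mod <- if (!is.null(mats$modulable))
      mats$modulable[idx] != 0 else rep(TRUE, nrow(idx))
    res[[cl]] <- data.frame(source = labs[idx[, "col"]],
                            target = labs[idx[, "row"]],
                            class = cl, modulable = mod)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Canonical edge names
#'
#' Edge identifiers of the form `"source->target"`, in the network's edge
#' order. Used to key per-edge parameters.
#'
#' @param net a `lep_network`.
#' @param modulable_only if TRUE, only edges flagged modulable.
#' @return character vector of edge names.
#' @export
edge_names <- function(net, modulable_only = FALSE) {
  e <- net$edges
  if (modulable_only) e <- e[e$modulable, , drop = FALSE]
  if (nrow(e) == 0L) return(character(0))
  paste0(e$source, "->", e$target)
}

#' @export
print.lep_network <- function(x, ...) {
  nh <- sum(!x$regions$observed)
  cat("LEP network:", nrow(x$regions), "regions (", nh, "hidden ),",
      nrow(x$edges), "directed edges\n")
  tab <- table(factor(x$edges$class,
                      levels = c("forward", "backward", "lateral")))
  cat("  forward:", tab[["forward"]], " backward:", tab[["backward"]],
      " lateral:", tab[["lateral"]], "\n")
  cat("  input at:", paste(x$input_regions, collapse = ", "), "\n")
  invisible(x)
}

#' Read/write a network as JSON
#'
#' The on-disk schema (version 1) is a JSON object with fields
#' `schema`, `regions` (label/observed/coordinates), `edges`
#' (source/target/class/modulable) and `input_regions`.
#'
#' @param net a `lep_network`.
#' @param path file path.
#' @return `write_network` returns `path` invisibly; `read_network`
#'   returns a `lep_network`.
#' @export
write_network <- function(net, path) {
  doc <- list(schema = "lep-network/1",
              regions = net$regions,
              edges = net$edges,
              input_regions = net$input_regions)
  jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "lep-network/1"))
    stop("unrecognised network schema: ", doc$schema)
  lep_network(doc$regions, doc$edges, doc$input_regions)
}
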