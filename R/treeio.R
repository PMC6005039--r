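#' Calibrated trees
#'
#' A calibrated tree couples a rooted binary topology (an \pkg{ape}
#' \code{phylo}) with a map from internal nodes to calibration densities.
#' Node ages, when present, are in units of 100 My with tips at age 0.
#'
#' In Newick files, calibrations are carried as single-quoted internal-node
#' labels in the form \code{'B(0.25, 0.337, 0.01, 0.1)'} — the same compact
#' strings used in published calibration tables.
#'
#' @param phylo a rooted binary \code{phylo} object.
#' @param calibrations named list of \code{calibration} objects; names are
#'   internal node numbers (ape numbering: tips \code{1..n}, root \code{n+1}).
#' @return An object of class \code{"calibrated_tree"}.
#' @export
calibrated_tree <- function(phylo, calibrations = list()) {
  stopifnot(inherits(phylo, "phylo"))
  if (!ape::is.rooted(phylo)) stop("tree must be rooted")
  if (!ape::is.binary(phylo)) stop("tree must be binary")
  n <- length(phylo$tip.label)
  if (anyDuplicated(phylo$tip.label))
    stop("duplicate tip names: ",
         paste(unique(phylo$tip.label[duplicated(phylo$tip.label)]),
               collapse = ", "))
  if (length(calibrations)) {
    ids <- as.integer(names(calibrations))
    if (anyNA(ids) || any(ids <= n) || any(ids > n + phylo$Nnode))
      stop("calibrations must attach to internal nodes only")
    if (anyDuplicated(ids)) stop("at most one calibration per node")
    ok <- vapply(calibrations, inherits, logical(1), "calibration")
    if (!all(ok)) stop("calibrations must be calibration objects")
  }
  structure(list(phylo = phylo, calibrations = calibrations),
            class = "calibrated_tree")
}

#' @export
print.calibrated_tree <- function(x, ...) {
  n <- length(x$phylo$tip.label)
  cat("Calibrated tree:", n, "tips,", x$phylo$Nnode, "internal nodes,",
      length(x$calibrations), "calibrated\n")
  for (nm in names(x$calibrations))
    cat("  node", nm, ":", format_calibration(x$calibrations[[nm]]), "\n")
  invisible(x)
}

## parent vector: parent[node] = parent node id, 0 for root
tree_parents <- function(phylo) {
  np <- integer(length(phylo$tip.label) + phylo$Nnode)
  np[phylo$edge[, 2]] <- phylo$edge[, 1]
  np
}

## list of children per node (empty integer for tips)
tree_children <- function(phylo) {
  nn <- length(phylo$tip.label) + phylo$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nn)) ch[[i]] <- integer(0)
  for (e in seq_len(nrow(phylo$edge)))
    ch[[phylo$edge[e, 1]]] <- c(ch[[phylo$edge[e, 1]]], phylo$edge[e, 2])
  ch
}

## internal nodes ordered so every child precedes its parent
postorder_nodes <- function(phylo) {
  e <- ape::reorder.phylo(phylo, "postorder")$edge
  unique(e[, 1])
}

#' Read a calibrated Newick tree
#'
#' Parses a rooted binary Newick string whose internal nodes may carry
#' calibration annotations as quoted labels, e.g.
#' \code{((A,B)'B(0.25,0.337,0.01,0.1)',C);}.
#'
#' @param text a Newick string, or \code{NULL} if \code{file} is given.
#' @param file path to a Newick file.
#' @return A \code{calibrated_tree}.
#' @export
read_calibrated_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file), collapse = "")
  no_quote <- gsub("'[^']*'", "", text)
  if (sum(strsplit(no_quote, "")[[1]] == "(") !=
      sum(strsplit(no_quote, "")[[1]] == ")"))
    stop("parse error: unbalanced parentheses")
  phylo <- ape::read.tree(text = text)
  if (is.null(phylo)) stop("parse error: not a valid Newick string")
  n <- length(phylo$tip.label)
  bad_tip <- grepl("^'?[A-Za-z0-9]+\\(.*\\)'?$", phylo$tip.label)
  if (any(bad_tip))
    stop("calibration annotation on a tip: ",
         paste(phylo$tip.label[bad_tip], collapse = ", "))
  cals <- list()
  if (!is.null(phylo$node.label)) {
    for (i in seq_along(phylo$node.label)) {
      lab <- gsub("^'|'$", "", phylo$node.label[i])
      lab <- gsub("_", " ", lab)
      if (!nzchar(lab)) next
      node <- n + i
      cal <- tryCatch(parse_calibration(lab), error = function(e)
        stop("calibration error at node ", node, ": ", conditionMessage(e),
             call. = FALSE))
      cals[[as.character(node)]] <- cal
    }
    phylo$node.label <- NULL
  }
  calibrated_tree(phylo, cals)
}

## recursive Newick writer preserving quoted calibration labels
newick_string <- function(phylo, node_labels = NULL, ages = NULL) {
  n <- length(phylo$tip.label)
  ch <- tree_children(phylo)
  rec <- function(node, parent_age) {
    bl <- if (!is.null(ages) && !is.na(parent_age))
      sprintf(":%.*g", 10, parent_age - ages[node]) else ""
    if (node <= n) return(paste0(phylo$tip.label[node], bl))
    sub <- vapply(ch[[node]], rec, character(1),
                  parent_age = if (is.null(ages)) NA_real_ else ages[node])
    lab <- if (!is.null(node_labels)) node_labels[node - n] else ""
    paste0("(", paste(sub, collapse = ","), ")", lab, bl)
  }
  paste0(rec(n + 1L, NA_real_), ";")
}

#' Write a calibrated Newick tree
#'
#' Inverse of [read_calibrated_newick()]; calibration parameters are written
#' with 8 significant digits. If node \code{ages} are supplied, branch
#' lengths (in 100 My) are written too.
#'
#' @param ct a \code{calibrated_tree}.
#' @param file optional output path; if missing the string is returned.
#' @param ages optional numeric vector of node ages indexed by node number.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_calibrated_newick <- function(ct, file = NULL, ages = NULL) {
  stopifnot(inherits(ct, "calibrated_tree"))
  n <- length(ct$phylo$tip.label)
  labs <- character(ct$phylo$Nnode)
  for (nm in names(ct$calibrations))
    labs[as.integer(nm) - n] <-
      paste0("'", format_calibration(ct$calibrations[[nm]]), "'")
  s <- newick_string(ct$phylo, labs, ages)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

## ---- alignments ----------------------------------------------------------

VALID_STATES <- c("A", "C", "G", "T", "-", "?")

normalize_states <- function(m) {
  m <- toupper(m)
  m[m == "U"] <- "T"
  m[!(m %in% VALID_STATES)] <- "?"
  m[m == "-"] <- "?"   # gaps treated as fully ambiguous in the likelihood
  m
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA (via \pkg{ape}) or relaxed PHYLIP (name, whitespace, sequence
#' per line) into a character matrix over \{A,C,G,T,?\}; ambiguity codes and
#' gaps are mapped to \code{?}. An optional partition table assigns each site
#' to a named partition.
#'
#' @param path file path.
#' @param format \code{"fasta"} or \code{"phylip"}.
#' @param partitions either \code{NULL} (one partition) or a data frame with
#'   columns \code{name}, \code{start}, \code{end} (1-based, inclusive,
#'   jointly covering every site).
#' @return An object of class \code{"alignment"}: list with \code{seq}
#'   (character matrix, rownames = tip names), \code{partition} (integer per
#'   site) and \code{part_names}.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"),
                           partitions = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    x <- ape::read.FASTA(path)
    lens <- lengths(x)
    if (length(unique(lens)) != 1)
      stop("format error: sequences have unequal lengths")
    m <- toupper(as.character(as.matrix(x)))
  } else {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln))]
    hdr <- scan(text = ln[1], what = numeric(), quiet = TRUE)
    if (length(hdr) == 2) ln <- ln[-1]
    parts <- strsplit(trimws(ln), "\\s+")
    nm <- vapply(parts, `[`, character(1), 1)
    sq <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
    if (length(unique(nchar(sq))) != 1)
      stop("format error: sequences have unequal lengths")
    m <- t(vapply(strsplit(sq, ""), identity, character(nchar(sq[1]))))
    rownames(m) <- nm
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate tip names in alignment")
  make_alignment(m, partitions)
}

#' @rdname read_alignment
#' @param seq character matrix of aligned sequences (rows = taxa).
#' @export
make_alignment <- function(seq, partitions = NULL) {
  seq <- normalize_states(as.matrix(seq))
  ns <- ncol(seq)
  if (ns == 0) stop("alignment has no sites")
  if (is.null(partitions)) {
    pidx <- rep(1L, ns); pnames <- "p1"
  } else {
    stopifnot(all(c("name", "start", "end") %in% names(partitions)))
    pidx <- rep(NA_integer_, ns)
    for (i in seq_len(nrow(partitions))) {
      rng <- partitions$start[i]:partitions$end[i]
      if (any(rng < 1 | rng > ns)) stop("partition outside alignment")
      pidx[rng] <- i
    }
    if (anyNA(pidx)) stop("partition table does not cover all sites")
    pnames <- as.character(partitions$name)
  }
  structure(list(seq = seq, partition = pidx, part_names = pnames),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("Alignment:", nrow(x$seq), "sequences x", ncol(x$seq), "sites,",
      length(x$part_names), "partition(s)\n")
  invisible(x)
}

#' Write an alignment to FASTA
#' @param aln an \code{alignment}.
#' @param file output path.
#' @export
write_alignment_fasta <- function(aln, file) {
  stopifnot(inherits(aln, "alignment"))
  con <- file(file, "w"); on.exit(close(con))
  for (i in seq_len(nrow(aln$seq)))
    writeLines(c(paste0(">", rownames(aln$seq)[i]),
                 paste(aln$seq[i, ], collapse = "")), con)
  invisible(file)
}

## ---- traces ----------------------------------------------------------------

#' Read and write MCMC traces
#'
#' Traces are tab-separated tables with a header; the log-likelihood column
#' \code{lnL} is mandatory. Values round-trip at 15 significant digits.
#'
#' @param trace a data frame with an \code{lnL} column.
#' @param path file path.
#' @return \code{read_trace} returns the data frame.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  if (!"lnL" %in% names(trace)) stop("trace is missing column 'lnL'")
  old <- options(digits = 15); on.exit(options(old))
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (!"lnL" %in% names(tr))
    stop("trace file is missing column 'lnL'")
  tr
}
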