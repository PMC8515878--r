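#' Read and validate a phylogeny
#'
#' Parses a rooted, binary phylogeny from a Newick string, a NEXUS TREES
#' block, or a file containing either.  The returned tree is an [ape::phylo]
#' object that has passed structural validation: a single root, strictly
#' bifurcating internal nodes, unique tip labels, and finite non-negative
#' branch lengths.  Branch lengths are interpreted as absolute time (Myr);
#' no unit conversion is attempted.
#'
#' @param text A character scalar: either the tree text itself or a path to
#'   a file.  NEXUS input is recognised by a leading `#NEXUS` token
#'   (case-insensitive); translate tables and quoted taxon names are
#'   supported via [ape::read.nexus()].
#' @return A validated `phylo` object.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @export
read_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  if (!grepl("[(;]", text) && file.exists(text)) {
    raw <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  check_newick_balance(raw)
  is_nexus <- grepl("^\\s*#nexus", raw, ignore.case = TRUE)
  tr <- tryCatch({
    if (is_nexus) {
      con <- textConnection(raw)
      on.exit(close(con), add = TRUE)
      out <- ape::read.nexus(con)
      if (inherits(out, "multiPhylo")) out <- out[[1L]]
      out
    } else {
      ape::read.tree(text = raw)
    }
  }, error = function(e) {
    stop("tree parse error: ", conditionMessage(e), call. = FALSE)
  })
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("tree parse error: input did not yield a tree", call. = FALSE)
  }
  validate_tree(tr)
  tr
}

# Cheap pre-scan so syntax errors carry a character offset, which ape's
# parser does not report.
check_newick_balance <- function(raw) {
  chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("tree parse error: unbalanced ')' at character offset ", i,
             call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("tree parse error: ", depth, " unclosed '(' at end of input ",
         "(character offset ", length(chars), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Structural validation of a phylogeny
#'
#' Asserts the invariants every downstream likelihood and simulation routine
#' relies on: rooted, strictly binary topology, unique tip labels, finite
#' non-negative branch lengths, and the node-count identity (n tips imply
#' n - 1 internal nodes).  Called automatically by [read_tree()].
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly; errors otherwise.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  n <- ape::Ntip(tree)
  if (n < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("validation error: duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (!ape::is.binary(tree)) {
    stop("unsupported topology: tree contains polytomies", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    stop("unsupported topology: tree is unrooted", call. = FALSE)
  }
  if (tree$Nnode != n - 1L) {
    stop("validation error: binary rooted tree with ", n,
         " tips must have ", n - 1L, " internal nodes, found ", tree$Nnode,
         call. = FALSE)
  }
  bl <- tree$edge.length
  if (is.null(bl)) stop("validation error: branch lengths required",
                        call. = FALSE)
  if (any(!is.finite(bl)) || any(bl < 0)) {
    stop("validation error: branch lengths must be finite and >= 0",
         call. = FALSE)
  }
  invisible(tree)
}

#' Check that a tree is ultrametric within a relative tolerance
#'
#' A time-calibrated tree should have all tips equidistant from the root.
#' Published chronograms carry rounding noise, so the check is relative:
#' it passes when the maximum absolute deviation of any tip depth from the
#' mean depth, divided by the mean depth, is at most `rel_tol`.  The default
#' 1e-4 accommodates the rounding typical of exported posterior trees while
#' still rejecting genuinely non-clock trees.
#'
#' @param tree A validated `phylo`.
#' @param rel_tol Maximum tolerated relative deviation (default `1e-4`).
#' @return A list of class `ultrametric_report` with elements `pass`,
#'   `max_rel_deviation`, `mean_depth`, and `offending_tips` (tips whose
#'   deviation exceeds the tolerance).
#' @examples
#' validate_ultrametric(read_tree("(A:1,B:1);"))$pass
#' @export
validate_ultrametric <- function(tree, rel_tol = 1e-4) {
  validate_tree(tree)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  mean_depth <- mean(depths)
  if (mean_depth <= 0) stop("degenerate tree: zero depth", call. = FALSE)
  rel_dev <- abs(depths - mean_depth) / mean_depth
  bad <- which(rel_dev > rel_tol)
  out <- list(pass = length(bad) == 0L,
              max_rel_deviation = max(rel_dev),
              mean_depth = mean_depth,
              offending_tips = tree$tip.label[bad])
  class(out) <- "ultrametric_report"
  out
}

#' @export
print.ultrametric_report <- function(x, ...) {
  cat(if (x$pass) "ultrametric: PASS" else "ultrametric: FAIL",
      sprintf(" (max relative deviation %.3g, mean depth %.6g)\n",
              x$max_rel_deviation, x$mean_depth))
  if (!x$pass) {
    cat("  offending tips:", paste(x$offending_tips, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a phylogeny to Newick or NEXUS
#'
#' @param tree A `phylo` object.
#' @param file Output path, or `""` to return the text.
#' @param format `"newick"` or `"nexus"`.
#' @return The file path (or tree text when `file = ""`), invisibly.
#' @export
write_tree <- function(tree, file = "", format = c("newick", "nexus")) {
  format <- match.arg(format)
  validate_tree(tree)
  if (format == "newick") {
    txt <- ape::write.tree(tree, digits = 12)
    if (file == "") return(invisible(txt))
    writeLines(txt, file)
  } else {
    if (file == "") {
      tf <- tempfile(fileext = ".nex")
      on.exit(unlink(tf), add = TRUE)
      ape::write.nexus(tree, file = tf, translate = TRUE)
      return(invisible(paste(readLines(tf), collapse = "\n")))
    }
    ape::write.nexus(tree, file = file, translate = TRUE)
  }
  invisible(file)
}

# Root age (mean tip depth) of a validated tree, in the branch-length unit.
tree_root_age <- function(tree) {
  mean(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}
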