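CHARACTERS <- c("drp", "crp", "dpf", "iip1", "iip2", "fp")
# iip1 is presence/absence; all others are 0/1/2 prominence grades
CHAR_MAX <- c(drp = 2L, crp = 2L, dpf = 2L, iip1 = 1L, iip2 = 2L, fp = 2L)

#' Construct a character matrix of ordinal skeletal scores
#'
#' Holds per-taxon integer scores for the six remex-attachment characters
#' (\code{drp}, \code{crp}, \code{dpf}, \code{iip1}, \code{iip2}, \code{fp}),
#' an extinct flag per taxon, and explicit missingness (\code{NA}; 0 is a
#' valid score, not a missing sentinel).
#'
#' @param scores integer matrix, taxa in rows (rownames = taxon labels),
#'   the six characters in columns. \code{NA} marks a missing cell.
#' @param extinct logical vector, one entry per taxon; default all extant.
#' @return an object of class \code{character_matrix}.
#' @export
character_matrix <- function(scores, extinct = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    stop("scores must have taxon rownames")
  if (nrow(scores) < 3L)
    stop("no taxa: a character matrix needs at least 3 taxa, got ",
         nrow(scores))
  if (anyDuplicated(rownames(scores)))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(scores)[duplicated(rownames(scores))]),
               collapse = ", "))
  if (ncol(scores) != length(CHARACTERS))
    stop("expected ", length(CHARACTERS), " character columns")
  colnames(scores) <- CHARACTERS
  storage.mode(scores) <- "integer"
  for (ch in CHARACTERS) {
    v <- scores[, ch]
    bad <- which(!is.na(v) & (v < 0L | v > CHAR_MAX[[ch]]))
    if (length(bad))
      stop("score out of range for character '", ch, "' (max ",
           CHAR_MAX[[ch]], ") in taxon: ", rownames(scores)[bad[1L]])
  }
  if (is.null(extinct)) extinct <- rep(FALSE, nrow(scores))
  extinct <- as.logical(extinct)
  stopifnot(length(extinct) == nrow(scores), !anyNA(extinct))
  names(extinct) <- rownames(scores)
  structure(list(scores = scores, extinct = extinct),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("character_matrix: ", nrow(x$scores), " taxa (",
      sum(!x$extinct), " extant, ", sum(x$extinct), " extinct), ",
      ncol(x$scores), " characters\n", sep = "")
  invisible(x)
}

#' Taxon labels of a character matrix
#' @param cm a \code{character_matrix}.
#' @param extant_only drop extinct taxa?
#' @return character vector of labels.
#' @export
taxa <- function(cm, extant_only = FALSE) {
  lab <- rownames(cm$scores)
  if (extant_only) lab[!cm$extinct] else lab
}

#' Read a character matrix from CSV
#'
#' The CSV must carry a header naming the six characters and one row per
#' taxon; an optional \code{extinct} column (0/1) flags fossil taxa.
#' Blank cells become missing values.
#'
#' @param path path to a CSV file.
#' @return a \code{character_matrix}.
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) stop("no taxa in ", path)
  taxon_col <- if ("taxon" %in% names(df)) "taxon" else names(df)[1L]
  missing_ch <- setdiff(CHARACTERS, names(df))
  if (length(missing_ch))
    stop("missing character columns: ", paste(missing_ch, collapse = ", "))
  sc <- matrix(NA_integer_, nrow(df), length(CHARACTERS),
               dimnames = list(df[[taxon_col]], CHARACTERS))
  for (ch in CHARACTERS) {
    raw <- trimws(df[[ch]])
    blank <- is.na(raw) | raw == ""
    num <- suppressWarnings(as.numeric(raw[!blank]))
    nonint <- which(is.na(num) | num != round(num))
    if (length(nonint))
      stop("non-integer score in column '", ch, "', row for taxon '",
           df[[taxon_col]][!blank][nonint[1L]], "'")
    sc[!blank, ch] <- as.integer(num)
  }
  extinct <- if ("extinct" %in% names(df))
    as.integer(df$extinct) > 0L else rep(FALSE, nrow(df))
  character_matrix(sc, extinct)
}

#' Write a character matrix to CSV
#' @param cm a \code{character_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_character_matrix <- function(cm, path) {
  df <- data.frame(taxon = rownames(cm$scores), cm$scores,
                   extinct = as.integer(cm$extinct),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a trait table of wing measurements
#'
#' Stores aspect ratio \eqn{AR = b^2/S} and mass \eqn{M} (kg) both raw and
#' log_e transformed; downstream modules consume the log_e values.  Extinct
#' taxa may lack both traits; a fossil-derived AR estimate can be kept as an
#' annotation that never enters the explanatory matrix.
#'
#' @param taxon taxon labels.
#' @param AR aspect ratio (dimensionless), \code{NA} allowed.
#' @param M mass in kg, \code{NA} allowed.
#' @param b wing span in m (optional).
#' @param S wing area in m^2 (optional).
#' @param AR_annotation fossil AR estimates held out of the model.
#' @return an object of class \code{trait_table} (a data.frame).
#' @export
trait_table <- function(taxon, AR, M, b = NULL, S = NULL,
                        AR_annotation = NULL) {
  n <- length(taxon)
  if (anyDuplicated(taxon)) stop("duplicate taxon labels in trait table")
  if (is.null(b)) b <- rep(NA_real_, n)
  if (is.null(S)) S <- rep(NA_real_, n)
  if (is.null(AR_annotation)) AR_annotation <- rep(NA_real_, n)
  AR <- as.numeric(AR); M <- as.numeric(M)
  derive <- is.na(AR) & !is.na(b) & !is.na(S)
  AR[derive] <- b[derive]^2 / S[derive]
  chk <- !is.na(AR) & !is.na(b) & !is.na(S)
  if (any(chk)) {
    relerr <- abs(b[chk]^2 / S[chk] - AR[chk]) / AR[chk]
    if (any(relerr > 0.01))
      stop("AR inconsistent with b^2/S (>1%) for taxon: ",
           taxon[chk][which(relerr > 0.01)[1L]])
  }
  if (any(!is.na(AR) & AR <= 0)) stop("AR must be positive")
  if (any(!is.na(M) & M <= 0)) stop("M must be positive")
  df <- data.frame(taxon = as.character(taxon), b = b, S = S,
                   AR = AR, M = M,
                   logAR = log(AR), logM = log(M),
                   AR_annotation = as.numeric(AR_annotation),
                   stringsAsFactors = FALSE)
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a trait table from CSV
#'
#' Expects columns \code{taxon}, \code{M}, and either \code{AR} or the pair
#' \code{b}, \code{S} from which AR is derived.  When a
#' \code{character_matrix} is supplied, taxa absent from it are kept with a
#' warning.
#'
#' @param path path to a CSV file.
#' @param cm optional \code{character_matrix} to cross-check taxon labels.
#' @return a \code{trait_table}.
#' @export
read_trait_table <- function(path, cm = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no taxa in ", path)
  taxon_col <- if ("taxon" %in% names(df)) "taxon" else names(df)[1L]
  get <- function(col) if (col %in% names(df)) as.numeric(df[[col]]) else NULL
  tt <- trait_table(df[[taxon_col]], AR = get("AR") %||% NA_real_,
                    M = get("M") %||% NA_real_,
                    b = get("b"), S = get("S"),
                    AR_annotation = get("AR_annotation"))
  if (!is.null(cm)) {
    extra <- setdiff(tt$taxon, taxa(cm))
    if (length(extra))
      warning("trait taxa absent from character matrix (retained): ",
              paste(extra, collapse = ", "))
  }
  tt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trait table to CSV
#' @param tt a \code{trait_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trait_table <- function(tt, path) {
  utils::write.csv(tt[, c("taxon", "b", "S", "AR", "M", "AR_annotation")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a set of rooted trees (Newick or Nexus)
#'
#' Every tree must contain all extant study taxa when a taxon universe is
#' given.  Tip matching is exact-label first, then unambiguous genus-prefix
#' (the character scores are coded at genus level); ambiguous genus matches
#' are an error.
#'
#' @param path path to a Newick (default) or Nexus tree file.
#' @param taxa character vector of study taxa each tree must cover
#'   (typically \code{taxa(cm, extant_only = TRUE)}).
#' @return an object of class \code{tree_set}: a list with \code{trees}
#'   (a \code{multiPhylo}), \code{count}, and the tip-matching report.
#' @export
read_tree_set <- function(path, taxa = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  first <- toupper(readLines(path, n = 1L, warn = FALSE))
  trees <- if (grepl("#NEXUS", first, fixed = TRUE))
    ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  tree_set(trees, taxa)
}

#' @rdname read_tree_set
#' @param trees a \code{phylo} or \code{multiPhylo} object.
#' @export
tree_set <- function(trees, taxa = NULL) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (!inherits(trees, "multiPhylo")) stop("trees must be phylo/multiPhylo")
  if (length(trees) < 1L) stop("tree set is empty")
  mapping <- NULL
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    if (!ape::is.rooted(tr)) stop("tree ", k, " is not rooted")
    if (is.null(tr$edge.length) || any(tr$edge.length < 0))
      stop("tree ", k, " lacks non-negative branch lengths")
    if (!is.null(taxa)) {
      m <- match_tree_tips(tr, taxa)
      if (anyNA(m$tip))
        stop("tree ", k, " is missing study taxa: ",
             paste(m$taxon[is.na(m$tip)], collapse = ", "))
      if (is.null(mapping)) mapping <- m
    }
  }
  structure(list(trees = trees, count = length(trees), mapping = mapping),
            class = "tree_set")
}

#' Match study taxa to tree tip labels
#'
#' Exact match first (spaces/underscores interchangeable), then genus
#' prefix; a genus matching several unclaimed tips is an error.
#'
#' @param tree a \code{phylo}.
#' @param taxa study taxon labels.
#' @return data.frame with columns \code{taxon}, \code{tip} (NA when
#'   unmatched) and \code{how} ("exact" or "genus").
#' @export
match_tree_tips <- function(tree, taxa) {
  tips <- tree$tip.label
  norm <- function(x) gsub("_", " ", x, fixed = TRUE)
  out <- data.frame(taxon = taxa, tip = NA_character_, how = NA_character_,
                    stringsAsFactors = FALSE)
  idx <- match(norm(taxa), norm(tips))
  out$tip[!is.na(idx)] <- tips[idx[!is.na(idx)]]
  out$how[!is.na(idx)] <- "exact"
  claimed <- out$tip[!is.na(out$tip)]
  for (i in which(is.na(out$tip))) {
    genus <- strsplit(norm(out$taxon[i]), " ")[[1L]][1L]
    cand <- setdiff(tips[startsWith(norm(tips), paste0(genus, " "))], claimed)
    if (length(cand) > 1L)
      stop("ambiguous genus match for '", out$taxon[i], "': ",
           paste(cand, collapse = ", "))
    if (length(cand) == 1L) {
      out$tip[i] <- cand; out$how[i] <- "genus"
      claimed <- c(claimed, cand)
    }
  }
  out
}

#' @export
print.tree_set <- function(x, ...) {
  cat("tree_set:", x$count, "tree(s),",
      length(x$trees[[1L]]$tip.label), "tips in first tree\n")
  invisible(x)
}

#' Load the packaged study dataset
#'
#' The published character scores, aspect ratios and masses for 74 taxa:
#' 71 extant taxa with complete traits and 3 extinct taxa (\emph{Ichthyornis
#' dispar}, \emph{Eocypselus rowei}, \emph{Parargornis messelensis}) scored
#' for all six characters but lacking model traits. Fossil AR estimates for
#' \emph{Eocypselus} (8.15) and \emph{Parargornis} (5.30) are stored as
#' annotations only and never enter the explanatory matrix.
#'
#' @return list with elements \code{characters} (a
#'   \code{character_matrix}) and \code{traits} (a \code{trait_table}).
#' @export
load_study_fixture <- function() {
  cdir <- system.file("extdata", package = "wingrda")
  cm <- read_character_matrix(file.path(cdir, "table1_characters.csv"))
  tt <- suppressWarnings(
    read_trait_table(file.path(cdir, "table1_traits.csv"), cm))
  list(characters = cm, traits = tt)
}

#' Checksums of the packaged fixture files
#' @return named character vector of md5 sums.
#' @export
fixture_checksums <- function() {
  cdir <- system.file("extdata", package = "wingrda")
  files <- c("table1_characters.csv", "table1_traits.csv")
  sums <- tools::md5sum(file.path(cdir, files))
  names(sums) <- files
  sums
}
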