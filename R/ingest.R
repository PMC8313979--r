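#' Column-name dialect for TF-gene tables
#'
#' Export dialects differ in how the TF, target-gene, cancer-type, regulatory
#' potential and correlation columns are labelled. The default mapping
#' matches the tab-delimited Cistrome Cancer export.
#'
#' @param tf,gene,cancer,rp,rho column names in the file header.
#' @return named character vector mapping internal field names to file
#'   column names.
#' @examples
#' cistromeDialect()
#' cistromeDialect(rp = "regulatory_potential")
#' @export
cistromeDialect <- function(tf = "TF", gene = "gene", cancer = "cancer",
                            rp = "RP", rho = "rho") {
    c(tf = tf, gene = gene, cancer = cancer, rp = rp, rho = rho)
}

.normSymbol <- function(x, uppercase = FALSE) {
    x <- trimws(as.character(x))
    if (uppercase) x <- toupper(x)
    x
}

.newTFGeneTable <- function(df) {
    rownames(df) <- NULL
    df$bp <- df$rp * df$rho
    new("TFGeneTable", records = df[, c("tf", "gene", "cancer",
                                        "rp", "rho", "bp")])
}

#' Read a TF-gene relationship table
#'
#' Reads a tab-delimited table of TF-to-gene regulatory relationships with
#' regulatory potential (RP) and Spearman correlation (rho) columns, in the
#' Cistrome Cancer export dialect or any dialect described by
#' [cistromeDialect()]. Either the table carries a cancer-type column
#' (pooled export) or the whole file belongs to one cancer type, given via
#' \code{cancer} or inferred from the file name.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param dialect column-name mapping, see [cistromeDialect()].
#' @param cancer optional single cancer code used when the file has no
#'   cancer column; defaults to the file base name in that case.
#' @param uppercase normalize symbols to upper case.
#' @return a [TFGeneTable-class]; row order follows the file.
#' @export
readTFGeneTable <- function(path, dialect = cistromeDialect(), cancer = NULL,
                            uppercase = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE,
                             quote = "", comment.char = "")
    needed <- dialect[c("tf", "gene", "rp", "rho")]
    missing <- needed[!needed %in% colnames(raw)]
    if (length(missing) > 0L)
        stop("configuration error: column(s) not found in ", path, ": ",
             paste(missing, collapse = ", "),
             " (adjust the dialect mapping)")
    df <- data.frame(tf = .normSymbol(raw[[dialect[["tf"]]]], uppercase),
                     gene = .normSymbol(raw[[dialect[["gene"]]]], uppercase),
                     rp = suppressWarnings(as.numeric(raw[[dialect[["rp"]]]])),
                     rho = suppressWarnings(as.numeric(raw[[dialect[["rho"]]]])),
                     stringsAsFactors = FALSE)
    if (dialect[["cancer"]] %in% colnames(raw)) {
        df$cancer <- .normSymbol(raw[[dialect[["cancer"]]]])
    } else {
        if (is.null(cancer))
            cancer <- sub("\\.[^.]*$", "", basename(path))
        df$cancer <- as.character(cancer)
    }
    bad <- which(is.na(df$rp) | is.na(df$rho))
    if (length(bad) > 0L)
        stop("validation error: non-numeric RP/rho at data row ", bad[1L],
             " of ", path)
    msg <- .validTFGeneRecords(df)
    if (!isTRUE(msg)) stop("validation error in ", path, ": ", msg)
    .newTFGeneTable(df)
}

#' Write a TF-gene relationship table
#'
#' Writes the records of a [TFGeneTable-class] as a tab-delimited file in
#' the same dialect read by [readTFGeneTable()], so that a read/write cycle
#' reproduces the records field-for-field.
#'
#' @param x a [TFGeneTable-class].
#' @param path output path.
#' @param dialect column-name mapping, see [cistromeDialect()].
#' @return \code{path}, invisibly.
#' @export
writeTFGeneTable <- function(x, path, dialect = cistromeDialect()) {
    stopifnot(is(x, "TFGeneTable"))
    df <- x@records[, c("tf", "gene", "cancer", "rp", "rho")]
    colnames(df) <- dialect[c("tf", "gene", "cancer", "rp", "rho")]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a gene list into a GeneSet
#'
#' Accepts one symbol per line or a single-column TSV (an optional header
#' line equal to the column name "gene" is tolerated). Symbols are
#' whitespace-trimmed and deduplicated.
#'
#' @param path path to the list file.
#' @param name name given to the resulting set.
#' @param uppercase normalize symbols to upper case.
#' @return a [GeneSet-class].
#' @export
readGeneList <- function(path, name = basename(path), uppercase = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    symbols <- .normSymbol(lines, uppercase)
    symbols <- symbols[nzchar(symbols)]
    if (length(symbols) > 1L && identical(tolower(symbols[1L]), "gene"))
        symbols <- symbols[-1L]
    symbols <- unique(symbols)
    if (length(symbols) == 0L)
        stop("validation error: empty gene list in ", path)
    new("GeneSet", name = name, members = symbols)
}

#' Read a gene-to-glycopathway classification
#'
#' Accepts either a two-column TSV (gene, pathway; one row per membership,
#' header optional) or a GMT file with one line per pathway. The
#' classification is many-to-many: a gene may belong to several pathways.
#'
#' @param path path to the classification file.
#' @param uppercase normalize gene symbols to upper case.
#' @return a [PathwayClassification-class].
#' @export
readPathwayClassification <- function(path, uppercase = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("validation error: empty file ", path)
    nf <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
    fields <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f)
        c(f, character(max(0L, 2L - length(f)))))   # keep trailing empties
    if (all(nf == 2L)) {
        df <- data.frame(gene = .normSymbol(vapply(fields, `[`, "", 1L),
                                            uppercase),
                         pathway = trimws(vapply(fields, `[`, "", 2L)),
                         stringsAsFactors = FALSE)
        if (identical(tolower(df$gene[1L]), "gene")) df <- df[-1L, ]
    } else if (all(nf >= 3L)) {
        # GMT: name, description, members...
        df <- do.call(rbind, lapply(fields, function(f) {
            data.frame(gene = .normSymbol(f[-c(1L, 2L)], uppercase),
                       pathway = trimws(f[1L]), stringsAsFactors = FALSE)
        }))
    } else {
        stop("format error: ", path, " is neither a two-column TSV nor GMT")
    }
    if (any(!nzchar(df$pathway)))
        stop("validation error: empty pathway name in ", path)
    if (any(!nzchar(df$gene)))
        stop("validation error: empty gene symbol in ", path)
    df <- unique(df)
    rownames(df) <- NULL
    new("PathwayClassification", membership = df)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then one or more member symbols.
#'
#' @param path path to the GMT file.
#' @param uppercase normalize member symbols to upper case.
#' @param source provenance string stored with the collection.
#' @return an [AnnotationCollection-class].
#' @export
readAnnotationGMT <- function(path, uppercase = FALSE,
                              source = basename(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("validation error: empty GMT ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nm <- vapply(fields, `[`, "", 1L)
    if (anyDuplicated(nm))
        stop("validation error: duplicate set name '",
             nm[duplicated(nm)][1L], "' in ", path)
    sets <- lapply(fields, function(f) {
        members <- .normSymbol(f[-c(1L, 2L)], uppercase)
        members <- unique(members[nzchar(members)])
        if (length(members) == 0L)
            stop("validation error: set '", f[1L], "' has no members in ",
                 path)
        members
    })
    names(sets) <- trimws(nm)
    new("AnnotationCollection", sets = sets, source = source)
}

#' Write an AnnotationCollection as GMT
#'
#' @param x an [AnnotationCollection-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationGMT <- function(x, path) {
    stopifnot(is(x, "AnnotationCollection"))
    lines <- vapply(names(x@sets), function(nm) {
        paste(c(nm, x@source, x@sets[[nm]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Packaged glycosylation pathway fixture
#'
#' Loads the classification of representative glycogenes into the 20
#' curated glycosylation pathways shipped with the package (glycolipid
#' core, gangliosides, dolichol pathway, sialylation, heparan sulfate
#' extension, and so on). The fixture covers the pathway names and
#' representative members (e.g., HAS1-HAS3 under hyaluronan synthesis); it
#' is not the full curated 208-gene classification.
#'
#' @return a [PathwayClassification-class] with 20 pathways.
#' @examples
#' pathwayNames(glycoPathwayFixture())
#' @export
glycoPathwayFixture <- function() {
    path <- system.file("extdata", "glyco_pathways.tsv",
                        package = "GlycoTFNet", mustWork = TRUE)
    readPathwayClassification(path)
}
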