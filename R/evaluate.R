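#' Map predicted clusters onto true classes
#'
#' Unlabeled clusters must be matched to the true classes before
#' misclassification can be counted.  The default \code{"majority"}
#' mapping sends each predicted cluster to the true class it overlaps
#' most (many-to-one: two clusters may map onto one class, as when two
#' predicted clusters jointly represent the normal tissues); overlap
#' ties break toward the lower class index.  \code{"one-to-one"}
#' maximizes the total overlap over injective assignments (enumerated
#' exhaustively; intended for small cluster counts).
#'
#' @param pred integer/factor predicted cluster labels.
#' @param true integer/factor true class labels, same length.
#' @param method \code{"majority"} (default) or \code{"one-to-one"}.
#' @return named vector: for each predicted cluster, the true class it
#'   maps to.
#' @export
mapClustersToClasses <- function(pred, true,
                                 method = c("majority", "one-to-one")) {
    method <- match.arg(method)
    if (length(pred) != length(true))
        stop("label vectors must have equal length")
    if (!length(pred)) stop("label vectors must be non-empty")
    tab <- table(pred, true)
    classes <- colnames(tab)
    if (method == "majority") {
        map <- classes[apply(tab, 1, which.max)]
    } else {
        if (nrow(tab) > 8L || ncol(tab) > 8L)
            stop("one-to-one mapping supported for at most 8 clusters/classes")
        # all ordered k-tuples from v without repetition
        arrangements <- function(v, k) {
            if (k == 0) return(list(integer(0)))
            out <- list()
            for (i in seq_along(v))
                for (rest in arrangements(v[-i], k - 1))
                    out <- c(out, list(c(v[i], rest)))
            out
        }
        take <- min(nrow(tab), ncol(tab))
        best <- -1; map <- NULL
        # clusters beyond the class count stay unmatched and count as
        # errors for every sample they contain
        for (rows in utils::combn(nrow(tab), take, simplify = FALSE)) {
            for (cols in arrangements(seq_len(ncol(tab)), take)) {
                score <- sum(tab[cbind(rows, cols)])
                if (score > best) {
                    best <- score
                    map <- rep(NA_character_, nrow(tab))
                    map[rows] <- classes[cols]
                }
            }
        }
    }
    names(map) <- rownames(tab)
    map
}

#' Misclassification error rate
#'
#' Proportion of samples whose predicted cluster, mapped onto the true
#' classes (see \code{\link{mapClustersToClasses}}), disagrees with
#' their true class.  Invariant under any permutation of the predicted
#' cluster labels.
#'
#' @inheritParams mapClustersToClasses
#' @param mapping mapping method passed on.
#' @return error rate in [0, 1].
#' @examples
#' errorRate(c(2, 2, 1, 1), c(1, 1, 2, 2))   # relabeling: 0
#' errorRate(c(1, 1, 1, 2), c(1, 1, 2, 2))   # 0.25
#' @export
errorRate <- function(pred, true, mapping = "majority") {
    map <- mapClustersToClasses(pred, true, mapping)
    mapped <- unname(map[as.character(pred)])
    mean(is.na(mapped) | mapped != as.character(true))
}

#' Sensitivity and specificity of a two-class clustering
#'
#' After mapping clusters onto the two true classes, sensitivity is the
#' fraction of true positives assigned to the positive class and
#' specificity the fraction of true negatives assigned to the negative
#' class.
#'
#' @inheritParams errorRate
#' @param positiveClass the class treated as positive (default: the
#'   first in sort order).
#' @return named numeric vector \code{c(SE = , SP = )}.
#' @export
sensitivitySpecificity <- function(pred, true, positiveClass = NULL,
                                   mapping = "majority") {
    classes <- sort(unique(true))
    if (length(classes) != 2L)
        stop("sensitivity/specificity require exactly two true classes")
    if (is.null(positiveClass)) positiveClass <- classes[1]
    map <- mapClustersToClasses(pred, true, mapping)
    mapped <- unname(map[as.character(pred)])
    pos <- as.character(true) == as.character(positiveClass)
    c(SE = mean(mapped[pos] == as.character(positiveClass)),
      SP = mean(mapped[!pos] != as.character(positiveClass), na.rm = FALSE))
}

#' Gene-selection error rate
#'
#' Binary classification error of the gene filter against the known
#' relevant genes: (false positives + false negatives) / p, with p the
#' total number of genes by default (\code{denominator = "relevant"}
#' divides by the number of relevant genes instead, for the alternative
#' reading).
#'
#' @param selected logical mask of selected genes.
#' @param relevant logical mask of truly relevant genes, same length.
#' @param denominator \code{"all"} (default) or \code{"relevant"}.
#' @return error rate (in [0, 1] for \code{"all"}).
#' @examples
#' geneSelectionError(c(TRUE, FALSE, TRUE, rep(FALSE, 7)),
#'                    c(TRUE, TRUE, rep(FALSE, 8)))   # 0.2
#' @export
geneSelectionError <- function(selected, relevant,
                               denominator = c("all", "relevant")) {
    denominator <- match.arg(denominator)
    if (length(selected) != length(relevant))
        stop("masks must have equal length")
    selected <- as.logical(selected); relevant <- as.logical(relevant)
    fp <- sum(selected & !relevant)
    fn <- sum(!selected & relevant)
    den <- if (denominator == "all") length(selected) else sum(relevant)
    (fp + fn) / den
}

#' Cluster-count frequencies over replicates
#'
#' CC is the fraction of replicates in which the detected number of
#' clusters equals the true one.  For three-cluster designs, CC2 and CC3
#' additionally report the fractions of replicates with exactly two and
#' exactly three detected clusters (two detected clusters typically
#' merge the two similar subgroups against the distinct one).
#'
#' @param mFound integer vector of detected cluster counts, one per
#'   replicate.
#' @param trueM the true number of clusters.
#' @return list with \code{CC}, the full distribution table
#'   (\code{byCount}), and \code{CC2}/\code{CC3} when \code{trueM == 3}.
#' @examples
#' clusterCountFrequencies(c(2, 3, 3, 2), 3)
#' @export
clusterCountFrequencies <- function(mFound, trueM) {
    if (!length(mFound)) stop("mFound must be non-empty")
    out <- list(CC = mean(mFound == trueM),
                byCount = table(mFound) / length(mFound))
    if (trueM == 3L) {
        out$CC2 <- mean(mFound == 2L)
        out$CC3 <- mean(mFound == 3L)
    }
    out
}
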