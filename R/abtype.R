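#' Ab10 cytological-type random-forest model
#'
#' Wraps a trained random forest over scaled tag-index bins together with its
#' training record: the 70/30 stratified split, the held-out accuracy, the
#' per-bin mean-decrease-Gini importances and the vote-confidence threshold.
#'
#' @aliases Ab10TypeModel-class
#' @export
setClass("Ab10TypeModel", representation(
    forest = "ANY", bins = "character", classes = "character",
    importance = "numeric", trainSamples = "character",
    testSamples = "character", heldOutAccuracy = "numeric",
    voteThreshold = "numeric"))

setMethod("show", "Ab10TypeModel", function(object) {
    cat("Ab10TypeModel:", length(object@bins), "bins,",
        length(object@classes), "classes (",
        paste(object@classes, collapse = ", "), ")\n",
        " trained on", length(object@trainSamples), "samples; held-out",
        length(object@testSamples), "samples, accuracy",
        round(100 * object@heldOutAccuracy, 1), "%\n",
        " vote threshold:", object@voteThreshold, "\n")
})

#' Train the Ab10-type random forest
#'
#' Trains a random forest to distinguish the Ab10 cytological types
#' (Ab10-I/II/III) from the scaled tag index of Ab10-region bins, using a
#' stratified 70/30 train/test split of the typed control samples, and
#' reports the held-out accuracy. Stratification guarantees every type is
#' present in the training split.
#'
#' @param scaled scaled tag-index matrix (bins x samples), covering at least
#'   the typed controls.
#' @param types named character/factor of Ab10 types for the control samples.
#' @param trainFraction fraction of each type used for training (default 0.7).
#' @param ntree trees in the forest (default 500).
#' @param voteThreshold minimum vote fraction for a non-ambiguous type call.
#' @param seed integer seed (split and forest are reproducible).
#' @return An [Ab10TypeModel-class].
#' @export
trainAb10TypeModel <- function(scaled, types, trainFraction = 0.7,
                               ntree = 500, voteThreshold = 0.65, seed = 1L) {
    types <- factor(unlist(types))
    names(types) <- if (!is.null(names(unlist(types)))) names(unlist(types))
                    else colnames(scaled)
    if (nlevels(droplevels(types)) < 2)
        stop("need at least two Ab10 types to train a classifier")
    tab <- table(types)
    if (any(tab < 2))
        stop("need at least 2 control samples per type; got: ",
             paste(names(tab), tab, sep = "=", collapse = ", "))
    set.seed(seed)
    train <- unlist(lapply(levels(types), function(tp) {
        ids <- names(types)[types == tp]
        sample(ids, max(1, round(trainFraction * length(ids))))
    }))
    test <- setdiff(names(types), train)
    x <- t(scaled[, train, drop = FALSE])
    fit <- randomForest::randomForest(x, droplevels(types[train]),
                                      ntree = ntree)
    acc <- if (length(test) > 0) {
        pred <- predict(fit, t(scaled[, test, drop = FALSE]))
        mean(as.character(pred) == as.character(types[test]))
    } else NA_real_
    imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
    new("Ab10TypeModel", forest = fit, bins = rownames(scaled),
        classes = levels(droplevels(types)),
        importance = setNames(as.numeric(imp), rownames(scaled)),
        trainSamples = train, testSamples = test,
        heldOutAccuracy = acc, voteThreshold = voteThreshold)
}

#' Type Ab10-positive samples with vote confidence
#'
#' Runs each sample down every tree of the forest; the predicted type is the
#' class with the largest vote fraction, accepted only when that fraction is
#' at least the model's vote threshold — otherwise the haplotype is
#' `"ambiguous"` (natural Ab10 diversity, including recombinants between
#' types, produces many intermediate profiles).
#'
#' @param model an [Ab10TypeModel-class].
#' @param scaled scaled tag-index matrix (same bins as training) covering the
#'   samples to type.
#' @param samples sample ids to type (default: all columns).
#' @return `data.frame` with `sample_id`, `predicted_type` and
#'   `top_vote_fraction`.
#' @export
predictAb10Types <- function(model, scaled, samples = colnames(scaled)) {
    x <- t(scaled[model@bins, samples, drop = FALSE])
    votes <- predict(model@forest, x, type = "vote", norm.votes = TRUE)
    top <- apply(votes, 1, max)
    type <- colnames(votes)[apply(votes, 1, which.max)]
    type[top < model@voteThreshold] <- "ambiguous"
    data.frame(sample_id = samples, predicted_type = type,
               top_vote_fraction = unname(top), row.names = NULL)
}

#' Bins ranked by mean decrease in Gini impurity
#'
#' The forest's most informative bins — those whose exclusion would hurt the
#' model most — are the diagnostic regions distinguishing Ab10 types.
#'
#' @param model an [Ab10TypeModel-class].
#' @param n how many bins to return (clamped to the feature count).
#' @return Named numeric vector of importances, decreasing, length `<= n`.
#' @export
topGiniBins <- function(model, n = 20) {
    imp <- sort(model@importance, decreasing = TRUE)
    head(imp, min(n, length(imp)))
}

#' PCA embedding of samples over diagnostic bins
#'
#' Principal-component embedding of the scaled tag index over the given bins
#' (typically the top-Gini bins), used to visualize the continuum of natural
#' Ab10 variation beyond the named types.
#'
#' @param scaled scaled tag-index matrix.
#' @param bins bins to embed over.
#' @param samples samples to embed (default: all columns).
#' @return A list with `coordinates` (samples x PCs) and `variance_fraction`
#'   (per-component fraction of total variance, non-increasing).
#' @export
ab10TypePCA <- function(scaled, bins, samples = colnames(scaled)) {
    x <- t(scaled[bins, samples, drop = FALSE])
    p <- prcomp(x, center = TRUE, scale. = FALSE)
    vf <- p$sdev^2 / sum(p$sdev^2)
    list(coordinates = p$x, variance_fraction = vf)
}
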