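#' Predict class labels
#'
#' @param model A fitted classifier (see [fitClassifier()]).
#' @param x Numeric samples x features matrix with the same feature
#'   columns used at fit time.
#' @return Factor of predicted labels with the model's class levels.
#' @seealso [predictScores()]
#' @export
setGeneric("predictLabels", function(model, x) standardGeneric("predictLabels"))

#' Predict per-class scores
#'
#' Returns a samples x classes score matrix: posterior probabilities for
#' LDA and naive Bayes, neighbor-vote fractions for KNN, and one-vs-rest
#' probabilities for the SVM. Rows for LDA/NBC/KNN sum to 1; higher score
#' means more likely class.
#'
#' @inheritParams predictLabels
#' @return Numeric samples x classes matrix, columns named by class.
#' @export
setGeneric("predictScores", function(model, x) standardGeneric("predictScores"))

#' @rdname modelToJSON
#' @export
setGeneric("modelToJSON", function(model) standardGeneric("modelToJSON"))
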