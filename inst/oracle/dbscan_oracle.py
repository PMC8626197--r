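"""Reference DBSCAN oracle used only by the test suite.

Reads a long-format CSV of many small instances
(instance,id,eps,min_pts,x1..x4; unused trailing dims empty) and writes
instance,id,core,label per point using scikit-learn's DBSCAN with the same
neighborhood convention (closed ball, self-inclusive min_pts).
"""
import sys

import pandas as pd
from sklearn.cluster import DBSCAN


def main(inp, out):
    df = pd.read_csv(inp)
    dims = [c for c in df.columns if c.startswith("x")]
    rows = []
    for inst, g in df.groupby("instance", sort=True):
        x = g[dims].dropna(axis=1, how="all").to_numpy()
        model = DBSCAN(eps=g["eps"].iloc[0], min_samples=int(g["min_pts"].iloc[0]))
        labels = model.fit_predict(x)
        core = set(model.core_sample_indices_)
        for i, (pid, lab) in enumerate(zip(g["id"], labels)):
            rows.append((inst, pid, int(i in core), int(lab)))
    pd.DataFrame(rows, columns=["instance", "id", "core", "label"]).to_csv(
        out, index=False
    )


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
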