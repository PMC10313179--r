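"""Per-frame optimal assignment oracle.

Reads a CSV of body-detection centroids (scenario, frame, cx, cy), solves
the linear sum assignment problem between every consecutive frame pair with
scipy, composes the per-frame permutations from the first frame, and writes
the resulting identity-chained positions: scenario, frame, track_id
(first-frame rank by (cy, cx)), cx, cy.
"""
import sys

import numpy as np
import pandas as pd
from scipy.optimize import linear_sum_assignment

inp, outp = sys.argv[1], sys.argv[2]
df = pd.read_csv(inp)
records = []
for scen, g in df.groupby("scenario"):
    frames = np.sort(g["frame"].unique())
    byf = {f: gg[["cx", "cy"]].to_numpy() for f, gg in g.groupby("frame")}
    p0 = byf[frames[0]]
    order = np.lexsort((p0[:, 0], p0[:, 1]))  # rank by (cy, cx)
    cur = order.copy()  # cur[r] = detection index of rank r at this frame
    prev = p0
    for f in frames:
        pts = byf[f]
        if f != frames[0]:
            diff = prev[:, None, :] - pts[None, :, :]
            cost = np.sqrt((diff ** 2).sum(axis=2))
            ri, ci = linear_sum_assignment(cost)
            perm = np.empty(len(ri), dtype=int)
            perm[ri] = ci
            cur = perm[cur]
            prev = pts
        for r in range(len(cur)):
            records.append((scen, f, r + 1, pts[cur[r], 0], pts[cur[r], 1]))

out = pd.DataFrame(records, columns=["scenario", "frame", "track_id", "cx", "cy"])
out.to_csv(outp, index=False)
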