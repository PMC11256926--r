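"""Sparse LP solve via scipy/HiGHS.

Reads a JSON problem {c, lb, ub, A_eq:{i,j,v}, b_eq, A_ub:{i,j,v}, b_ub}
(1-based triplet indices) from argv[1], writes {status, objective, x,
message} JSON to argv[2]. status: 0 optimal, 2 infeasible (scipy codes).
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog
from scipy.sparse import coo_matrix


def as_mat(trip, nrow, ncol):
    if trip is None or nrow == 0 or len(trip.get("i", [])) == 0:
        return None
    return coo_matrix(
        (trip["v"], (np.asarray(trip["i"]) - 1, np.asarray(trip["j"]) - 1)),
        shape=(nrow, ncol),
    ).tocsc()


def main():
    with open(sys.argv[1]) as fh:
        prob = json.load(fh)
    n = len(prob["c"])
    b_eq = prob.get("b_eq") or []
    b_ub = prob.get("b_ub") or []
    A_eq = as_mat(prob.get("A_eq"), len(b_eq), n)
    A_ub = as_mat(prob.get("A_ub"), len(b_ub), n)
    res = linprog(
        c=np.asarray(prob["c"], dtype=float),
        A_ub=A_ub,
        b_ub=np.asarray(b_ub, dtype=float) if A_ub is not None else None,
        A_eq=A_eq,
        b_eq=np.asarray(b_eq, dtype=float) if A_eq is not None else None,
        bounds=list(zip(prob["lb"], prob["ub"])),
        method="highs",
        options={"presolve": True},
    )
    out = {
        "status": int(res.status),
        "objective": None if res.fun is None else float(res.fun),
        "x": None if res.x is None else [float(v) for v in res.x],
        "message": str(res.message),
    }
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
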