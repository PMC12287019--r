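classifier,param,split,accuracy,precision,recall,f1
knn,3,30-70,74.55,77.65,86.45,81.63
knn,3,40-60,77.89,80.55,88.09,84.04
knn,3,50-50,80.97,85.50,87.92,86.70
knn,3,60-40,85.20,87.60,90.10,88.65
knn,3,70-30,93.16,96.02,93.67,94.52
knn,3,80-20,96.92,98.89,95.97,97.25
knn,5,30-70,73.41,74.77,90.44,81.74
knn,5,40-60,75.79,76.40,91.79,83.25
knn,5,50-50,78.71,79.56,93.04,85.54
knn,5,60-40,76.00,78.11,90.09,83.47
knn,5,70-30,80.53,82.16,92.41,86.57
knn,5,80-20,81.54,86.27,89.74,87.60
knn,7,30-70,73.18,71.91,96.26,82.03
knn,7,40-60,76.32,76.20,94.68,84.04
knn,7,50-50,78.39,79.70,93.26,85.78
knn,7,60-40,80.40,83.59,90.39,86.67
knn,7,70-30,82.11,82.89,96.03,88.81
knn,7,80-20,86.15,91.71,91.86,91.49
knn,9,30-70,75.23,72.95,98.28,83.57
knn,9,40-60,75.00,73.87,96.06,83.41
knn,9,50-50,78.71,80.32,92.85,85.80
knn,9,60-40,82.40,83.31,94.45,88.39
knn,9,70-30,84.21,88.56,91.98,89.92
knn,9,80-20,91.54,91.28,99.09,94.92
knn,11,30-70,74.77,73.49,96.54,83.33
knn,11,40-60,75.26,73.52,97.36,83.60
knn,11,50-50,77.74,76.95,96.21,85.38
knn,11,60-40,80.40,81.60,93.94,87.14
knn,11,70-30,81.58,87.06,97.80,92.18
knn,11,80-20,87.69,89.95,95.17,92.11
svm,linear,30-70,95.72,96.36,97.10,96.54
svm,linear,40-60,96.19,96.24,97.60,96.89
svm,linear,50-50,97.42,98.10,98.04,98.02
svm,linear,60-40,98.00,98.16,98.86,98.46
svm,linear,70-30,96.58,97.27,95.53,96.69
svm,linear,80-20,98.15,98.89,95.53,97.11
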