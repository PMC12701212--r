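ranker,rank,feature
t_test,1,Area
t_test,2,Major Axis Length
t_test,3,Minor Axis Length
t_test,4,Convex Area
t_test,5,Filled Area
t_test,6,Equivalent Diameter
t_test,7,Contrast STD D2
t_test,8,Mean Intensity
t_test,9,Energy STD D1
t_test,10,Correlation 0 D2
t_test,11,Energy 0 D3
t_test,12,Contrast 135 D3
t_test,13,Energy 135 D3
t_test,14,Correlation Mean D3
t_test,15,Homogeneity 135 D3
t_test,16,Homogeneity Mean D3
t_test,17,Smoothness
mrmr,1,Minor Axis Length
mrmr,2,Euler Number
mrmr,3,Solidity
mrmr,4,Contrast STD D1
mrmr,5,Energy STD D1
mrmr,6,Homogeneity STD D1
mrmr,7,Perimeter
mrmr,8,STD
mrmr,9,Contrast 135 D2
mrmr,10,Energy Mean D2
mrmr,11,Contrast 45 D3
mrmr,12,Energy 90 D3
mrmr,13,Correlation 135 D3
mrmr,14,Energy 135 D3
mrmr,15,Homogeneity 0 D3
mrmr,16,Circularity
mrmr,17,Compactness
mrmr,18,Breast Density
importance_extra_trees,1,Area
importance_extra_trees,2,Minor Axis Length
importance_extra_trees,3,Convex Area
importance_extra_trees,4,Filled Area
importance_extra_trees,5,Euler Number
importance_extra_trees,6,Equivalent Diameter
importance_extra_trees,7,Max Intensity
importance_extra_trees,8,Homogeneity STD D1
importance_extra_trees,9,Energy 135 D2
importance_extra_trees,10,Energy 45 D2
importance_extra_trees,11,Energy 45 D3
importance_extra_trees,12,Correlation 45 D3
importance_extra_trees,13,Energy STD D3
importance_extra_trees,14,Homogeneity 135 D3
importance_extra_trees,15,Homogeneity 0 D3
importance_extra_trees,16,Shape Ratio
importance_random_forest,1,Area
importance_random_forest,2,Minor Axis Length
importance_random_forest,3,Euler Number
importance_random_forest,4,Equivalent Diameter
importance_random_forest,5,Solidity
importance_random_forest,6,Perimeter
importance_random_forest,7,Energy STD D1
importance_random_forest,8,Energy 45 D2
importance_random_forest,9,Correlation 90 D2
importance_random_forest,10,Energy 0 D3
importance_random_forest,11,Contrast STD D3
importance_random_forest,12,Energy STD D2
importance_random_forest,13,Energy 135 D3
importance_random_forest,14,Energy 90 D3
importance_random_forest,15,Homogeneity Mean D3
importance_random_forest,16,Circularity
importance_random_forest,17,Homogeneity STD D3
importance_gradient_boosting,1,Area
importance_gradient_boosting,2,Minor Axis Length
importance_gradient_boosting,3,Euler Number
importance_gradient_boosting,4,Perimeter
importance_gradient_boosting,5,Contrast 45 D1
importance_gradient_boosting,6,Correlation STD D1
importance_gradient_boosting,7,Contrast 45 D2
importance_gradient_boosting,8,Energy Mean D2
importance_gradient_boosting,9,Contrast 90 D3
importance_gradient_boosting,10,Energy STD D1
importance_gradient_boosting,11,Energy 45 D3
importance_gradient_boosting,12,Correlation 135 D3
importance_gradient_boosting,13,Energy Mean D3
importance_gradient_boosting,14,Energy STD D3
importance_gradient_boosting,15,Circularity
importance_gradient_boosting,16,Compactness
univariate_k_best,1,Area
univariate_k_best,2,Major Axis Length
univariate_k_best,3,Minor Axis Length
univariate_k_best,4,Convex Area
univariate_k_best,5,Filled Area
univariate_k_best,6,Equivalent Diameter
univariate_k_best,7,Min Intensity
univariate_k_best,8,Energy 135 D2
univariate_k_best,9,Homogeneity STD D2
univariate_k_best,10,Variance
univariate_k_best,11,Energy 135 D3
univariate_k_best,12,Homogeneity 135 D3
univariate_k_best,13,Homogeneity 45 D3
univariate_k_best,14,Homogeneity Mean D3
univariate_k_best,15,Shape Ratio
sequential_forward,1,Orientation
sequential_forward,2,Convex Area
sequential_forward,3,Euler Number
sequential_forward,4,Solidity
sequential_forward,5,Extent
sequential_forward,6,Mean Intensity
sequential_forward,7,Energy 45 D2
sequential_forward,8,Homogeneity 45 D2
sequential_forward,9,STD
sequential_forward,10,Energy STD D2
sequential_forward,11,Homogeneity 135 D2
sequential_forward,12,Energy 90 D3
sequential_forward,13,Compactness
sequential_forward,14,Energy 45 D3
sequential_forward,15,Homogeneity STD D3
sequential_forward,16,Circularity
sequential_forward,17,Shape Ratio
sequential_backward,1,Area
sequential_backward,2,Filled Area
sequential_backward,3,Euler Number
sequential_backward,4,Perimeter
sequential_backward,5,Shape Ratio
sequential_backward,6,Energy STD D2
sequential_backward,7,Max Intensity
sequential_backward,8,Homogeneity STD D1
sequential_backward,9,Homogeneity 45 D2
sequential_backward,10,Energy 45 D3
sequential_backward,11,Circularity
sequential_backward,12,Energy Mean D3
sequential_backward,13,Energy STD D3
sequential_backward,14,Homogeneity 135 D3
sequential_backward,15,Compactness
sequential_backward,16,Smoothness
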