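year,sex,age_lo,age_hi,count
2015,F,50,55,107851.92746663766
2015,F,55,60,83614.0366981831
2015,F,60,65,65183.49413950558
2015,F,65,70,49357.136998711474
2015,F,70,75,47828.082978904764
2015,F,75,80,36990.784420986194
2015,F,80,85,30376.06736069589
2015,F,85,90,26133.170961354877
2015,F,90,95,21298.22500090857
2015,F,95,NA,17267.166421946007
2015,M,50,55,96916.27829525493
2015,M,55,60,82756.40503317388
2015,M,60,65,64488.49771634594
2015,M,65,70,59714.89041131624
2015,M,70,75,45963.23416745518
2015,M,75,80,35583.85675813756
2015,M,80,85,31150.677863554185
2015,M,85,90,25866.01254978875
2015,M,90,95,21038.450585411316
2015,M,95,NA,16507.953880433237
2020,F,50,55,119077.24270403344
2020,F,55,60,92316.65279652427
2020,F,60,65,71967.84456492781
2020,F,65,70,54494.267461189804
2020,F,70,75,52806.06827086542
2020,F,75,80,40840.81497452049
2020,F,80,85,33537.63284965442
2020,F,85,90,28853.13238517561
2020,F,90,95,23514.961365737454
2020,F,95,NA,19064.346972130217
2020,M,50,55,107003.4023833798
2020,M,55,60,91369.75813897114
2020,M,60,65,71200.5123558246
2020,M,65,70,65930.06416832602
2020,M,70,75,50747.124497273595
2020,M,75,80,39287.453150478264
2020,M,80,85,34392.865435817366
2020,M,85,90,28558.167911552042
2020,M,90,95,23228.149420424437
2020,M,95,NA,18226.114979497284
2030,F,50,55,145154.4944045782
2030,F,55,60,112533.48463155651
2030,F,60,65,87728.40094369704
2030,F,65,70,66428.20795689225
2030,F,70,75,64370.30256404715
2030,F,75,80,49784.7255619788
2030,F,80,85,40882.187303561615
2030,F,85,90,35171.807376899094
2030,F,90,95,28664.606691226254
2030,F,95,NA,23239.332579870683
2030,M,50,55,130436.55042579368
2030,M,55,60,111379.2253276764
2030,M,60,65,86793.02726251795
2030,M,65,70,80368.3803310857
2030,M,70,75,61860.46159295578
2030,M,75,80,47891.18616623846
2030,M,80,85,41924.71105389193
2030,M,85,90,34812.24732945528
2030,M,90,95,28314.984530301845
2030,M,95,NA,22217.532458190053
2040,F,50,55,176942.5187163411
2040,F,55,60,137177.68982843318
2040,F,60,65,106940.4312254295
2040,F,65,70,80975.61482970299
2040,F,70,75,78467.03963894771
2040,F,75,80,60687.30266102252
2040,F,80,85,49835.15820022213
2040,F,85,90,42874.23693357044
2040,F,90,95,34941.99560794919
2040,F,95,NA,28328.616739264733
2040,M,50,55,159001.42713240732
2040,M,55,60,135770.65417777628
2040,M,60,65,105800.21592746224
2040,M,65,70,97968.6071676099
2040,M,70,75,75407.5575001131
2040,M,75,80,58379.0887035748
2040,M,80,85,51105.98883458679
2040,M,85,90,42435.935242083375
2040,M,90,95,34515.80814467583
2040,M,95,NA,27083.04809258608
2050,F,50,55,215691.9429750377
2050,F,55,60,167218.83844863164
2050,F,60,65,130359.78893563167
2050,F,65,70,98708.82263305267
2050,F,70,75,95650.8834733847
2050,F,75,80,73977.48330831944
2050,F,80,85,60748.77976562675
2050,F,85,90,52263.4555835555
2050,F,90,95,42594.09766957138
2050,F,95,NA,34532.42573133379
2050,M,50,55,193821.85244560754
2050,M,55,60,165503.66984174718
2050,M,60,65,128969.87284981694
2050,M,65,70,119423.18547197485
2050,M,70,75,91921.39181807167
2050,M,75,80,71163.78337403666
2050,M,80,85,62297.91521767566
2050,M,85,90,51729.16826735851
2050,M,90,95,42074.577529969436
2050,M,95,NA,33014.08450131209
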